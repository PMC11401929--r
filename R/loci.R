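# Collapse a genome-wide scan into independent genomic risk loci
# (FUMA-style clumping with spelled-out defaults), compare loci across
# studies positionally, and classify proxy-based replication calls.

#' Clump a scan into independent genomic risk loci
#'
#' FUMA-convention clumping: independent significant SNPs are
#' genome-wide-significant SNPs mutually independent at `r2 < r2_candidate`
#' (greedy, ascending p); lead SNPs are the subset mutually independent at
#' `r2 < r2_lead`; every SNP in the table with `r2 >= r2_candidate` to an
#' independent significant SNP joins its locus as a candidate member; loci
#' whose candidate spans are closer than `merge_kb` on the same chromosome
#' are merged, with the new lead the smallest-p member (ties broken by
#' larger `|beta|`, then lexicographic snp_id). The locus span is the
#' min/max position of member candidate SNPs.
#'
#' @param sumstats summary-statistic data.frame (needs snp_id, chromosome,
#'   base_pair_location, beta, p_value and/or mlog10_p).
#' @param ld square LD matrix of r values with SNP-id dimnames covering at
#'   least every significant SNP (r is squared internally).
#' @param sig genome-wide significance threshold on p.
#' @param r2_candidate,r2_lead r-squared thresholds for candidate
#'   membership and lead independence.
#' @param merge_kb merge distance in kilobases.
#' @return a `locus_set`: list with `table` (locus_id, chr, start, end,
#'   lead_snp, lead_p, lead_mlog10_p, lead_beta, n_members) and `members`
#'   (named list of member snp_id vectors).
#' @export
clump_loci <- function(sumstats, ld, sig = 5e-8,
                       r2_candidate = 0.6, r2_lead = 0.1, merge_kb = 250) {
  ss <- sumstats
  if (!"mlog10_p" %in% names(ss)) ss$mlog10_p <- -log10(ss$p_value)
  ss <- ss[is.finite(ss$mlog10_p), , drop = FALSE]
  sig_mask <- ss$mlog10_p > -log10(sig)
  sig_ss <- ss[sig_mask, , drop = FALSE]
  if (!nrow(sig_ss)) {
    return(structure(list(table = data.frame(), members = list()),
                     class = "locus_set"))
  }
  missing_ld <- setdiff(sig_ss$snp_id, colnames(ld))
  if (length(missing_ld))
    stop("LD matrix missing significant SNP(s): ",
         paste(missing_ld, collapse = ", "))
  R2 <- ld^2

  # order: ascending p (= descending -log10 p), ties by |beta| then id
  ord <- order(-sig_ss$mlog10_p, -abs(sig_ss$beta), sig_ss$snp_id)
  sig_ss <- sig_ss[ord, , drop = FALSE]

  indep <- character(0)
  assign_to <- character(nrow(sig_ss)); names(assign_to) <- sig_ss$snp_id
  for (i in seq_len(nrow(sig_ss))) {
    s <- sig_ss$snp_id[i]
    same_chr <- indep[sig_ss$chromosome[match(indep, sig_ss$snp_id)] ==
                        sig_ss$chromosome[i]]
    r2s <- if (length(same_chr)) R2[s, same_chr] else numeric(0)
    if (length(r2s) && any(r2s >= r2_candidate)) {
      assign_to[s] <- same_chr[which.max(r2s)]
    } else {
      indep <- c(indep, s)
      assign_to[s] <- s
    }
  }

  # candidate members: any SNP in the table (present in LD) with
  # r2 >= r2_candidate to an independent significant SNP
  in_ld <- intersect(ss$snp_id, colnames(ld))
  members <- lapply(indep, function(s) {
    cand <- in_ld[R2[s, in_ld] >= r2_candidate]
    union(s, cand)
  })
  names(members) <- indep

  # group independent significant SNPs under leads at r2_lead
  lead_of <- character(0)
  leads <- character(0)
  for (s in indep) {  # indep is already in ascending-p order
    same_chr <- leads[sig_ss$chromosome[match(leads, sig_ss$snp_id)] ==
                        sig_ss$chromosome[match(s, sig_ss$snp_id)]]
    r2s <- if (length(same_chr)) R2[s, same_chr] else numeric(0)
    if (length(r2s) && any(r2s >= r2_lead)) {
      lead_of[s] <- same_chr[which.max(r2s)]
    } else {
      leads <- c(leads, s)
      lead_of[s] <- s
    }
  }

  # initial loci: one per lead, members pooled over its independent SNPs
  loci <- lapply(leads, function(l) {
    grp <- names(lead_of)[lead_of == l]
    mem <- unique(unlist(members[grp], use.names = FALSE))
    pos <- ss$base_pair_location[match(mem, ss$snp_id)]
    list(lead = l, members = mem,
         chr = ss$chromosome[match(l, ss$snp_id)],
         start = min(pos, na.rm = TRUE), end = max(pos, na.rm = TRUE))
  })

  # merge loci on the same chromosome closer than merge_kb (span gap)
  pick_lead <- function(cands) {
    sub <- ss[match(cands, ss$snp_id), , drop = FALSE]
    sub <- sub[order(-sub$mlog10_p, -abs(sub$beta), sub$snp_id), , drop = FALSE]
    sub$snp_id[1]
  }
  repeat {
    merged <- FALSE
    if (length(loci) > 1) {
      ordl <- order(vapply(loci, `[[`, numeric(1), "chr"),
                    vapply(loci, `[[`, numeric(1), "start"))
      loci <- loci[ordl]
      for (i in seq_len(length(loci) - 1L)) {
        a <- loci[[i]]; b <- loci[[i + 1L]]
        if (a$chr == b$chr && (b$start - a$end) <= merge_kb * 1000) {
          loci[[i]] <- list(
            lead = pick_lead(c(a$lead, b$lead)),
            members = unique(c(a$members, b$members)),
            chr = a$chr, start = min(a$start, b$start),
            end = max(a$end, b$end))
          loci[[i + 1L]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }

  ordl <- order(vapply(loci, `[[`, numeric(1), "chr"),
                vapply(loci, `[[`, numeric(1), "start"))
  loci <- loci[ordl]
  tab <- do.call(rbind, lapply(seq_along(loci), function(i) {
    l <- loci[[i]]
    li <- match(l$lead, ss$snp_id)
    data.frame(locus_id = sprintf("locus_%03d", i),
               chr = l$chr, start = l$start, end = l$end,
               lead_snp = l$lead,
               lead_p = ss$p_value[li],
               lead_mlog10_p = ss$mlog10_p[li],
               lead_beta = ss$beta[li],
               n_members = length(l$members),
               stringsAsFactors = FALSE)
  }))
  mem <- lapply(loci, `[[`, "members")
  names(mem) <- tab$locus_id
  structure(list(table = tab, members = mem), class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("locus_set with %d loci\n", nrow(x$table)))
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Attach per-trait lead p-values to a locus set
#'
#' Looks up the ratio-scan lead SNP of each locus in the component-trait
#' scans, storing `-log10 p` for the ratio, TG and HDL traits (the boost
#' score inputs).
#'
#' @param loci a `locus_set` from the ratio-trait scan.
#' @param ss_tg,ss_hdl component-trait summary statistics.
#' @return the `locus_set` with `mlog10p_tghdl`, `mlog10p_tg`,
#'   `mlog10p_hdl` columns added to its table.
#' @export
add_component_pvalues <- function(loci, ss_tg, ss_hdl) {
  tab <- loci$table
  tab$mlog10p_tghdl <- tab$lead_mlog10_p
  tab$mlog10p_tg <- ss_tg$mlog10_p[match(tab$lead_snp, ss_tg$snp_id)]
  tab$mlog10p_hdl <- ss_hdl$mlog10_p[match(tab$lead_snp, ss_hdl$snp_id)]
  loci$table <- tab
  loci
}

#' Positional overlap of external study leads with locus boundaries
#'
#' An external lead overlaps a locus iff the chromosome matches and
#' `start <= pos <= end` (both boundaries inclusive).
#'
#' @param loci a `locus_set`.
#' @param external_leads data.frame with columns study, snp_id, chr, pos.
#' @return list with `hits` (study x locus membership table),
#'   `per_study` (loci overlapped per study), and `intersections`
#'   (counts of loci per exact study combination, the upset structure).
#' @export
locus_overlap <- function(loci, external_leads) {
  tab <- loci$table
  studies <- unique(external_leads$study)
  hit <- matrix(FALSE, nrow(tab), length(studies),
                dimnames = list(tab$locus_id, studies))
  for (k in seq_len(nrow(external_leads))) {
    e <- external_leads[k, ]
    ov <- tab$chr == e$chr & tab$start <= e$pos & tab$end >= e$pos
    hit[ov, e$study] <- TRUE
  }
  per_study <- colSums(hit)
  combo <- apply(hit, 1L, function(r)
    if (any(r)) paste(studies[r], collapse = "&") else "none")
  intersections <- as.data.frame(table(combo), stringsAsFactors = FALSE)
  names(intersections) <- c("studies", "n_loci")
  list(hits = as.data.frame(hit), per_study = per_study,
       intersections = intersections)
}

#' Harmonize a replication record to discovery allele orientation
#'
#' @return list(beta, ok, ambiguous): beta sign-flipped when effect/other
#'   alleles are swapped; palindromic SNPs (A/T or C/G) with frequency
#'   near 0.5 are flagged ambiguous and never auto-flipped.
#' @noRd
harmonize_alleles <- function(ea_d, oa_d, ea_r, oa_r, eaf_r, beta_r,
                              palindrome_band = c(0.4, 0.6)) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  pal <- ea_d %in% names(comp) && identical(unname(comp[ea_d]), oa_d)
  if (pal && !is.na(eaf_r) &&
      eaf_r > palindrome_band[1] && eaf_r < palindrome_band[2]) {
    return(list(beta = NA_real_, ok = FALSE, ambiguous = TRUE))
  }
  same <- function(a, b) a == b | (!is.na(comp[a]) & comp[a] == b)
  if (same(ea_d, ea_r) && same(oa_d, oa_r)) {
    list(beta = beta_r, ok = TRUE, ambiguous = FALSE)
  } else if (same(ea_d, oa_r) && same(oa_d, ea_r)) {
    list(beta = -beta_r, ok = TRUE, ambiguous = FALSE)
  } else {
    list(beta = NA_real_, ok = FALSE, ambiguous = FALSE)
  }
}

#' Proxy-based locus replication calls
#'
#' For each locus, the lead SNP is looked up in the replication table; if
#' absent, the member SNP with the smallest discovery p that is present is
#' used as a proxy. After allele harmonization the call is `robust` if
#' `p_rep < 0.05 / n_tested`, else `nominal` if `p_rep < 0.05`, else
#' `direction_only` if the discovery and replication effects agree in
#' sign, else `discordant`; loci with no member present (or only
#' strand-ambiguous palindromic proxies) are `untestable`.
#'
#' @param loci a `locus_set`.
#' @param discovery,replication summary-statistic tables.
#' @param n_tested number of loci tested (Bonferroni denominator);
#'   defaults to the number of testable loci.
#' @param alpha nominal level.
#' @return data.frame of replication calls.
#' @export
proxy_replication <- function(loci, discovery, replication,
                              n_tested = NULL, alpha = 0.05) {
  tab <- loci$table
  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    mem <- loci$members[[tab$locus_id[i]]]
    dsub <- discovery[match(mem, discovery$snp_id), , drop = FALSE]
    dsub <- dsub[!is.na(dsub$snp_id), , drop = FALSE]
    dsub <- dsub[order(dsub$p_value), , drop = FALSE]
    # lead first, then next most significant members
    lead <- tab$lead_snp[i]
    cand <- unique(c(lead, dsub$snp_id))
    cand <- cand[cand %in% replication$snp_id]
    proxy <- NA_character_; class <- "untestable"
    beta_d <- NA_real_; beta_r <- NA_real_; p_r <- NA_real_; amb <- FALSE
    for (s in cand) {
      di <- match(s, discovery$snp_id)
      ri <- match(s, replication$snp_id)
      h <- harmonize_alleles(discovery$effect_allele[di],
                             discovery$other_allele[di],
                             replication$effect_allele[ri],
                             replication$other_allele[ri],
                             replication$effect_allele_frequency[ri],
                             replication$beta[ri])
      if (h$ambiguous) { amb <- TRUE; next }
      if (!h$ok) next
      proxy <- s
      beta_d <- discovery$beta[di]
      beta_r <- h$beta
      p_r <- replication$p_value[ri]
      break
    }
    rows[[i]] <- data.frame(
      locus_id = tab$locus_id[i], proxy_snp = proxy,
      beta_discovery = beta_d, beta_replication = beta_r,
      p_replication = p_r, ambiguous_skipped = amb,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  testable <- !is.na(out$proxy_snp)
  if (is.null(n_tested)) n_tested <- sum(testable)
  thr <- alpha / n_tested
  cls <- rep("untestable", nrow(out))
  cls[testable & out$p_replication < thr] <- "robust"
  cls[testable & out$p_replication >= thr & out$p_replication < alpha] <- "nominal"
  weak <- testable & out$p_replication >= alpha
  cls[weak & sign(out$beta_discovery) == sign(out$beta_replication)] <- "direction_only"
  cls[weak & sign(out$beta_discovery) != sign(out$beta_replication)] <- "discordant"
  out$class <- cls
  out$n_tested <- n_tested
  out
}

#' Write a locus table as TSV
#'
#' Columns: locus_id, chr, start, end, lead_snp, n_members and whichever
#' per-trait `-log10 p` columns are present.
#'
#' @param loci a `locus_set`.
#' @param path output path.
#' @export
write_loci <- function(loci, path) write_tsv(loci$table, path)
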