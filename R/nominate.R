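# SNP-to-gene nomination with an explicit annotation precedence
# (coding > promoter > fine-mapped eQTL > regulatory > nearest gene),
# direction-of-effect calls from coding deleteriousness or eQTL/GWAS
# concordance, and colocalization by approximate Bayes factors.

ANNOTATION_TIERS <- c(exonic_missense = "exonic", exonic_utr5 = "exonic",
                      exonic_utr3 = "exonic", promoter = "promoter",
                      finemapped_eqtl = "eqtl", regulatory = "regulatory")
TIER_ORDER <- c("exonic", "promoter", "eqtl", "regulatory")
ANNOTATION_LABELS <- c(exonic_missense = "Exonic",
                       exonic_utr5 = "Exonic (5_prime_UTR_variant)",
                       exonic_utr3 = "Exonic (3_prime_UTR_variant)",
                       promoter = "Promoter",
                       finemapped_eqtl = "Fine-mapped eQTL",
                       regulatory = "Regulatory variant")

#' Nominate the candidate causal gene at a fine-mapped locus
#'
#' Causal SNPs (PIP above threshold) are evaluated in descending PIP
#' order; the first SNP carrying any usable annotation nominates the
#' target gene of its highest-precedence annotation
#' (exonic > promoter > fine-mapped eQTL > regulatory). If no causal SNP
#' carries an annotation, the gene whose body is nearest the highest-PIP
#' SNP is nominated (distance 0 if inside; ties broken by nearest
#' strand-aware TSS, then lexicographic gene name).
#'
#' @param causal data.frame with snp_id, pip, chr, pos for SNPs with
#'   PIP above threshold (>= 1 row).
#' @param annotations data.frame: snp_id, category, gene, votes,
#'   eqtl_beta, tissue. Categories outside the known vocabulary (or
#'   "none") are ignored.
#' @param gene_models data.frame: gene, chr, start, end, strand
#'   (1-based closed, as from [read_gene_models()]).
#' @return list: `gene`, `evidence_tier` ("exonic", "promoter", "eqtl",
#'   "regulatory" or "nearest"), `causal_snp`, `pip`, `annotation_label`
#'   (combined, Table-style, e.g. "Promoter; Fine-mapped eQTL").
#' @export
nominate_gene <- function(causal, annotations, gene_models) {
  assert_that(nrow(causal) >= 1, "need at least one causal SNP")
  assert_that(!is.null(gene_models) && nrow(gene_models) >= 1,
              "empty gene model set")
  causal <- causal[order(-causal$pip, causal$snp_id), , drop = FALSE]
  ann <- annotations[annotations$category %in% names(ANNOTATION_TIERS), ,
                     drop = FALSE]
  for (i in seq_len(nrow(causal))) {
    hits <- ann[ann$snp_id == causal$snp_id[i], , drop = FALSE]
    if (!nrow(hits)) next
    tier <- ANNOTATION_TIERS[hits$category]
    best <- order(match(tier, TIER_ORDER), hits$category)[1]
    label <- paste(ANNOTATION_LABELS[unique(hits$category[
      order(match(tier, TIER_ORDER))])], collapse = "; ")
    return(list(gene = hits$gene[best], evidence_tier = unname(tier[best]),
                causal_snp = causal$snp_id[i], pip = causal$pip[i],
                annotation_label = label))
  }
  # fallback: nearest gene to the highest-PIP SNP
  top <- causal[1, ]
  gm <- gene_models[gene_models$chr == top$chr, , drop = FALSE]
  assert_that(nrow(gm) >= 1, "no gene models on the causal SNP's chromosome")
  body_dist <- pmax(gm$start - top$pos, top$pos - gm$end, 0)
  tss <- ifelse(gm$strand == "-", gm$end, gm$start)
  tss_dist <- abs(top$pos - tss)
  ord <- order(body_dist, tss_dist, gm$gene)
  list(gene = gm$gene[ord[1]], evidence_tier = "nearest",
       causal_snp = top$snp_id, pip = top$pip,
       annotation_label = "Nearest gene")
}

#' Direction-of-effect call for a nominated gene
#'
#' For coding (missense) causal variants with at least `vote_threshold`
#' deleteriousness votes, the variant approximates loss of function:
#' a positive trait beta means LOF raises the ratio (`LOF_harmful`), a
#' negative beta means LOF lowers it (`LOF_protective`). For fine-mapped
#' eQTL variants the call is the concordance of the eQTL and GWAS
#' effects: same sign means expression raises the trait. UTR-only or
#' otherwise unusable evidence yields `indeterminate`.
#'
#' @param nomination output of [nominate_gene()].
#' @param annotations annotation table (same layout as above).
#' @param gwas_beta effect-allele-oriented trait effect of the causal SNP.
#' @param vote_threshold minimum deleteriousness votes (of 5 tools) for a
#'   missense variant to count as LOF-like. Default 1 (any tool).
#' @return list: `gene`, `call` in \{LOF_harmful, LOF_protective,
#'   expression_raises_trait, expression_lowers_trait, indeterminate\},
#'   `evidence`.
#' @export
direction_of_effect <- function(nomination, annotations, gwas_beta,
                                vote_threshold = 1) {
  snp <- nomination$causal_snp
  ann <- annotations[annotations$snp_id == snp, , drop = FALSE]
  mk <- function(call, ev) list(gene = nomination$gene, call = call,
                                evidence = ev)
  if (is.na(gwas_beta) || gwas_beta == 0) {
    warning("GWAS beta is zero or missing; direction indeterminate")
    return(mk("indeterminate", "no usable trait effect"))
  }
  mis <- ann[ann$category == "exonic_missense", , drop = FALSE]
  if (nrow(mis) && any(mis$votes >= vote_threshold)) {
    call <- if (gwas_beta > 0) "LOF_harmful" else "LOF_protective"
    return(mk(call, sprintf("deleterious missense (%d/5 votes), beta = %.3g",
                            max(mis$votes), gwas_beta)))
  }
  eq <- ann[ann$category == "finemapped_eqtl" & !is.na(ann$eqtl_beta), ,
            drop = FALSE]
  if (nrow(eq)) {
    s <- sign(eq$eqtl_beta[1] * gwas_beta)
    call <- if (s > 0) "expression_raises_trait" else "expression_lowers_trait"
    return(mk(call, sprintf("eQTL beta = %.3g (%s), GWAS beta = %.3g",
                            eq$eqtl_beta[1], eq$tissue[1] %||% "NA", gwas_beta)))
  }
  mk("indeterminate", "no coding-deleterious or eQTL evidence")
}

#' Colocalization of two traits by approximate Bayes factors
#'
#' Per-SNP Wakefield approximate Bayes factors for each trait, combined
#' into posterior probabilities of the five standard hypotheses under a
#' single causal variant per trait: H0 no association, H1/H2 one trait
#' only, H3 two distinct causal variants, H4 one shared causal variant.
#' The overlap call is `PP.H3 + PP.H4 >= overlap_threshold`, which flags
#' loci where both traits carry a genuine signal whether or not it is the
#' same variant.
#'
#' @param beta1,se1,beta2,se2 per-SNP effects and standard errors of the
#'   two traits over the same SNP window (aligned).
#' @param p1,p2,p12 prior probabilities that a SNP is associated with
#'   trait 1 only, trait 2 only, or both.
#' @param sd_prior prior effect SD of the Wakefield approximation
#'   (0.15, the quantitative-trait default).
#' @param overlap_threshold threshold on `PP.H3 + PP.H4`.
#' @return list: `pp` (named PP.H0..PP.H4 summing to 1), `overlap`
#'   logical, `low_confidence` (TRUE for windows of < 2 SNPs), `n_snps`.
#' @export
coloc_abf <- function(beta1, se1, beta2, se2,
                      p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      sd_prior = 0.15, overlap_threshold = 0.99) {
  assert_that(length(beta1) == length(beta2) &&
                length(beta1) == length(se1) && length(beta2) == length(se2),
              "both traits must cover the same SNP window")
  assert_that(all(se1 > 0) && all(se2 > 0), "standard errors must be > 0")
  W <- sd_prior^2
  labf <- function(b, se) {
    r <- W / (W + se^2)
    0.5 * (log(1 - r) + r * (b / se)^2)
  }
  l1 <- labf(beta1, se1)
  l2 <- labf(beta2, se2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  # sum over i != j of exp(l1_i + l2_j), in log space
  s3 <- logdiffexp(s1 + s2, s12)
  lh <- c(H0 = 0,
          H1 = log(p1) + s1,
          H2 = log(p2) + s2,
          H3 = log(p1) + log(p2) + s3,
          H4 = log(p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP.", names(lh))
  list(pp = pp,
       overlap = unname(pp["PP.H3"] + pp["PP.H4"]) >= overlap_threshold,
       low_confidence = length(beta1) < 2,
       n_snps = length(beta1))
}
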