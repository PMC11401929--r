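toy_genes <- function() {
  data.frame(gene = c("G1", "G2", "G3"),
             chr = c(1, 1, 1),
             start = c(1000, 8000, 20000),
             end = c(3000, 9000, 21000),
             strand = c("+", "-", "+"),
             stringsAsFactors = FALSE)
}

ann_row <- function(snp, cat, gene, votes = 0, eqtl_beta = NA, tissue = NA) {
  data.frame(snp_id = snp, category = cat, gene = gene, votes = votes,
             eqtl_beta = eqtl_beta, tissue = tissue, stringsAsFactors = FALSE)
}

no_ann <- data.frame(snp_id = character(0), category = character(0),
                     gene = character(0), votes = integer(0),
                     eqtl_beta = numeric(0), tissue = character(0),
                     stringsAsFactors = FALSE)

test_that("annotation precedence and pip ordering drive gene nomination", {
  causal <- data.frame(snp_id = c("v1", "v2"), pip = c(0.9, 0.4),
                       chr = 1, pos = c(2000, 8500))
  # coding evidence on the top SNP beats an eQTL on a lower-pip SNP
  ann <- rbind(ann_row("v1", "exonic_missense", "G1", votes = 5),
               ann_row("v2", "finemapped_eqtl", "G2", eqtl_beta = 0.3,
                       tissue = "adipose"))
  nom <- nominate_gene(causal, ann, toy_genes())
  expect_identical(nom$gene, "G1")
  expect_identical(nom$evidence_tier, "exonic")
  expect_identical(nom$causal_snp, "v1")

  # precedence within one SNP: exonic beats regulatory; combined label kept
  ann2 <- rbind(ann_row("v1", "regulatory", "G2"),
                ann_row("v1", "exonic_missense", "G1", votes = 3))
  nom2 <- nominate_gene(causal, ann2, toy_genes())
  expect_identical(nom2$gene, "G1")
  expect_match(nom2$annotation_label, "Exonic; Regulatory variant")

  # an eQTL-only causal SNP nominates through the eqtl tier
  ann3 <- ann_row("v1", "finemapped_eqtl", "G2", eqtl_beta = -0.4,
                  tissue = "muscle")
  nom3 <- nominate_gene(causal, ann3, toy_genes())
  expect_identical(nom3$gene, "G2")
  expect_identical(nom3$evidence_tier, "eqtl")

  # annotation input order never matters
  nom2b <- nominate_gene(causal, ann2[2:1, ], toy_genes())
  expect_identical(nom2b, nom2)
})

test_that("unannotated loci fall back to the nearest gene with tie rules", {
  causal <- data.frame(snp_id = "v1", pip = 0.8, chr = 1, pos = 2500)
  empty_ann <- no_ann
  nom <- nominate_gene(causal, empty_ann, toy_genes())
  expect_identical(nom$gene, "G1")              # inside G1's body
  expect_identical(nom$evidence_tier, "nearest")
  expect_identical(nom$annotation_label, "Nearest gene")

  # between G1 (ends 3000) and G2 (starts 8000): closer to G1
  causal$pos <- 4000
  expect_identical(nominate_gene(causal, empty_ann, toy_genes())$gene, "G1")

  # equidistant bodies: nearest strand-aware TSS decides
  genes <- data.frame(gene = c("A", "B"), chr = 1,
                      start = c(100, 900), end = c(400, 1200),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  causal$pos <- 650  # 250 from both bodies; TSS A = 100 (d 550), TSS B = 1200 (d 550)
  nomt <- nominate_gene(causal, empty_ann, genes)
  expect_identical(nomt$gene, "A")  # full tie resolved lexicographically

  expect_error(nominate_gene(causal, empty_ann, toy_genes()[0, ]), "empty")
})

test_that("direction-of-effect calls follow the concordance rules", {
  causal <- data.frame(snp_id = "v1", pip = 1, chr = 1, pos = 2000)
  genes <- toy_genes()

  # deleterious missense lowering the ratio: LOF is protective
  ann <- ann_row("v1", "exonic_missense", "G1", votes = 4)
  nom <- nominate_gene(causal, ann, genes)
  expect_identical(direction_of_effect(nom, ann, -0.25)$call, "LOF_protective")
  expect_identical(direction_of_effect(nom, ann, 0.25)$call, "LOF_harmful")
  # negating every trait beta flips harmful and protective
  for (b in c(-0.4, 0.1, 2)) {
    a <- direction_of_effect(nom, ann, b)$call
    bb <- direction_of_effect(nom, ann, -b)$call
    expect_setequal(c(a, bb), c("LOF_harmful", "LOF_protective"))
  }
  # below the vote threshold the coding route is unusable
  ann0 <- ann_row("v1", "exonic_missense", "G1", votes = 0)
  nom0 <- nominate_gene(causal, ann0, genes)
  expect_identical(direction_of_effect(nom0, ann0, -0.25)$call,
                   "indeterminate")

  # eQTL concordance: higher expression, lower trait
  anne <- ann_row("v1", "finemapped_eqtl", "G2", eqtl_beta = 0.3,
                  tissue = "adipose")
  nome <- nominate_gene(causal, anne, genes)
  expect_identical(direction_of_effect(nome, anne, -0.05)$call,
                   "expression_lowers_trait")
  expect_identical(direction_of_effect(nome, anne, 0.05)$call,
                   "expression_raises_trait")

  # UTR-only evidence stays indeterminate
  annu <- ann_row("v1", "exonic_utr3", "G1")
  nomu <- nominate_gene(causal, annu, genes)
  expect_identical(direction_of_effect(nomu, annu, -0.02)$call,
                   "indeterminate")

  # zero beta warns and is indeterminate
  expect_warning(out <- direction_of_effect(nom, ann, 0), "indeterminate")
  expect_identical(out$call, "indeterminate")
})

test_that("colocalization posteriors are normalized and match direct enumeration", {
  se <- rep(0.1, 5)
  # identical strong signals at the same SNP: shared causal variant
  b1 <- c(0.8, 0.02, -0.01, 0.03, 0)
  out <- coloc_abf(b1, se, b1, se)
  expect_equal(sum(out$pp), 1, tolerance = 1e-8)
  expect_gt(out$pp["PP.H4"], 0.99)
  expect_true(out$overlap)

  # strong signals at two different, uncorrelated SNPs: H3 dominates,
  # still an overlap under the H3 + H4 rule
  b2 <- c(0.01, 0.8, 0, -0.02, 0.01)
  out2 <- coloc_abf(b1, se, b2, se)
  expect_gt(out2$pp["PP.H3"], 0.9)
  expect_true(out2$overlap)

  # direct plain-arithmetic enumeration oracle (moderate z: no underflow)
  W <- 0.15^2
  abf <- function(b, s) {
    r <- W / (W + s^2)
    sqrt(1 - r) * exp(0.5 * r * (b / s)^2)
  }
  a1 <- abf(b1, se); a2 <- abf(b2, se)
  p1 <- 1e-4; p2 <- 1e-4; p12 <- 1e-5
  h <- c(1, p1 * sum(a1), p2 * sum(a2),
         p1 * p2 * (sum(a1) * sum(a2) - sum(a1 * a2)),
         p12 * sum(a1 * a2))
  expect_equal(unname(out2$pp), h / sum(h), tolerance = 1e-8)

  # null data: H0 wins, no overlap call
  out0 <- coloc_abf(rep(0.01, 5), se, rep(-0.01, 5), se)
  expect_gt(out0$pp["PP.H0"], 0.9)
  expect_false(out0$overlap)

  # a window of one SNP computes but is flagged low-confidence
  out1 <- coloc_abf(0.8, 0.1, 0.8, 0.1)
  expect_true(out1$low_confidence)
})

test_that("raising the shared prior never decreases PP.H4", {
  set.seed(15)
  b1 <- stats::rnorm(8, 0, 0.2); b2 <- b1 + stats::rnorm(8, 0, 0.05)
  se <- rep(0.08, 8)
  p12s <- c(1e-7, 1e-6, 1e-5, 1e-4)
  h4 <- vapply(p12s, function(p12)
    unname(coloc_abf(b1, se, b2, se, p12 = p12)$pp["PP.H4"]), numeric(1))
  expect_true(all(diff(h4) >= -1e-12))
})
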