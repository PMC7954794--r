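# DMS scoring: frequencies, pseudolog ratios, synonymous scaling,
# classification, aa-level aggregation, two-PPI categories.

test_that("pseudocounted frequencies follow the stated arithmetic", {
  tab <- data.frame(condition = "reference", replicate = 1L, position = 1L,
                    codon = c("GCT", "GCC", "GCA"), count = c(10, 0, 25),
                    depth = 1000, wt_codon = "GCT")
  f <- variant_frequencies(tab)
  expect_equal(f$freq, c(10.5, 0.5, 25.5) / 1000)
  expect_true(all(f$freq > 0))
  f0 <- variant_frequencies(tab, pseudocount = 0)
  expect_equal(f0$freq, c(10, 0, 25) / 1000)
  tab$depth <- 0
  expect_warning(variant_frequencies(tab), "zero depth")
})

test_that("log ratios match hand-evaluated pseudocounted values", {
  mk <- function(cond, counts, depth) {
    data.frame(condition = cond, replicate = 1L, position = 1L,
               codon = c("GCT", "GCC"), count = counts, depth = depth,
               wt_codon = "GCT")
  }
  sel <- variant_frequencies(mk("selection", c(0, 20), 1000))
  ref <- variant_frequencies(mk("reference", c(10, 20), 1000))
  r <- variant_log_ratios(sel, ref)
  # dropout variant: log2(0.5 / 10.5)
  expect_equal(r$ratio[r$codon == "GCT"], log2(0.5 / 10.5))
  expect_equal(r$ratio[r$codon == "GCC"], 0)

  # doubling one condition's depth with equal counts shifts by exactly -1
  sel2 <- variant_frequencies(mk("selection", c(10, 20), 2000))
  r2 <- variant_log_ratios(sel2, ref)
  expect_equal(r2$ratio, r_equal <- log2((c(10.5, 20.5) / 2000) /
                                         (c(10.5, 20.5) / 1000)))
  expect_equal(unique(round(r2$ratio, 12)), -1)
})

test_that("synonymous median is exactly zero after scaling", {
  sim <- gen_dms_counts(c("GCT", "CGT", "TTA", "TCT"), depth = 3000,
                        n_reps = 2, seed = 13)
  vs <- dms_scores_from_counts(sim$counts)
  expect_identical(median(vs$dms_score[vs$is_synonymous]), 0)
  expect_true(all(vs$n_replicates == 2L))
  # synonymous flag: same aa as WT, different codon
  expect_true(all(vs$aa[vs$is_synonymous] == vs$wt_aa[vs$is_synonymous]))
  expect_false(any(vs$is_wt & vs$is_synonymous))
})

test_that("a constant shift of all synonymous ratios nullifies their scores", {
  r <- data.frame(position = 1L,
                  codon = c("GCT", "GCC", "GCA", "GCG", "TGG"),
                  wt_codon = "GCT", replicate = 1L,
                  ratio = c(0, 1.3, 1.3, 1.3, -2))
  vs <- dms_scores(r)
  expect_equal(vs$dms_score[vs$is_synonymous], c(0, 0, 0))
  # a variant whose ratio equals the synonymous median scores 0
  r2 <- rbind(r, data.frame(position = 1L, codon = "AAA", wt_codon = "GCT",
                            replicate = 1L, ratio = 1.3))
  vs2 <- dms_scores(r2)
  expect_equal(vs2$dms_score[vs2$codon == "AAA"], 0)
})

test_that("scores are invariant to scaling counts and depths together", {
  sim <- gen_dms_counts(c("GCT", "CGT"), depth = 2000, n_reps = 1, seed = 5)
  counts <- sim$counts
  scaled <- counts
  sel <- scaled$condition == "selection"
  scaled$count[sel] <- scaled$count[sel] * 4L
  scaled$depth[sel] <- scaled$depth[sel] * 4L
  s1 <- dms_scores_from_counts(counts)
  s2 <- dms_scores_from_counts(scaled)
  expect_equal(s2$dms_score, s1$dms_score, tolerance = 0.01)
})

test_that("percentile classification calls ~2% of synonymous variants", {
  sim <- gen_dms_counts(rep(c("GCT", "CGT", "TTA", "TCT", "GGT"), 6),
                        depth = 3000, n_reps = 2, seed = 31)
  vs <- classify_variants(dms_scores_from_counts(sim$counts))
  syn <- vs[vs$is_synonymous, ]
  rate <- mean(syn$class != "neutral")
  expect_lt(abs(rate - 0.02), 2 / nrow(syn) + 0.02)
  # far-below outlier is deleterious
  thr <- attr(vs, "thresholds")
  expect_true(all(vs$class[vs$dms_score < thr["low"] - 1] == "deleterious"))
})

test_that("aa aggregation averages codons and recovers aa-level effects", {
  r <- data.frame(position = 1L,
                  codon = c("TTA", "TTG", "CTT", "GCT", "GCC", "GCA", "TGG"),
                  wt_codon = "GCT", replicate = 1L,
                  ratio = c(-1, -3, -2, 0, 0.2, 0.2, 0.4))
  vs <- dms_scores(r)
  aa <- aggregate_to_aa(vs)
  # L encoded by three scored codons: mean of their scores
  expect_equal(aa$score[aa$aa == "L"],
               mean(vs$dms_score[vs$codon %in% c("TTA", "TTG", "CTT")]))
  # single-codon aa (W) equals its codon score
  expect_equal(aa$score[aa$aa == "W"], vs$dms_score[vs$codon == "TGG"])
  # two codons scoring -1 and -3 average to -2 on the shifted scale
  expect_equal(mean(vs$dms_score[vs$codon %in% c("TTA", "CTT")]),
               mean(c(-1, -2)) - 0.2)
  # WT codon excluded from aggregation; only true substitutions counted
  expect_equal(aa$n_codons[aa$aa == "A"], 2L)  # GCC + GCA, not WT GCT
})

test_that("two-PPI categories partition substitutions by the two thresholds", {
  eff1 <- data.frame(position = 1L, codon = c("TTA", "TTG"), effect = -4)
  eff2 <- data.frame(position = 1L, codon = c("CCT", "CCA"), effect = -4)
  s1 <- dms_scores_from_counts(
    gen_dms_counts("GCT", depth = 5000, effects = eff1, seed = 8)$counts)
  s2 <- dms_scores_from_counts(
    gen_dms_counts("GCT", depth = 5000, effects = eff2, seed = 9)$counts)
  # a single WT position has only 3 synonymous codons: both PPIs warn
  # about threshold stability
  w <- capture_warnings(
    cats <- assign_categories(s1, s2, labels = c("hua2", "lsb3")))
  expect_length(w, 2L)
  expect_match(w, "unstable", all = TRUE)
  expect_setequal(unique(cats$category),
                  intersect(unique(cats$category),
                            c("destabilize_both", "destabilize_hua2_only",
                              "destabilize_lsb3_only",
                              "neutral_or_increasing")))
  expect_identical(cats$category[cats$aa == "L"], "destabilize_hua2_only")
  expect_identical(cats$category[cats$aa == "P"], "destabilize_lsb3_only")
  expect_true(all(table(paste(cats$position, cats$aa)) == 1L))
})
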