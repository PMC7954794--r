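# DHFR-PCA plate scoring: normalization, PCA scores, calls, dependency
# classes, growth scores.

test_that("plate normalization centers the background and is idempotent", {
  g <- toy_plate(list(a = c(5, 5, 5), b = c(5, 5)))
  n1 <- normalize_plate(g)
  expect_true(all(n1$log2_size == 0))

  set.seed(1)
  g2 <- toy_plate(list(a = rnorm(9, 10), b = rnorm(8, 10)))
  n2 <- normalize_plate(g2)
  expect_equal(median(n2$log2_size[!n2$is_border & n2$qc_pass]), 0)
  # idempotence: background of a normalized plate is 0
  expect_equal(normalize_plate(n2)$log2_size, n2$log2_size)
})

test_that("background override replaces the measured background", {
  g <- toy_plate(list(a = c(10, 11)))
  g$qc_pass <- FALSE  # undetectable background
  expect_error(normalize_plate(g), "no qc-passing")
  n <- normalize_plate(g, background_override = 9.5)
  expect_equal(n$log2_size, c(0.5, 1.5))
  expect_equal(attr(n, "background"), 9.5)
})

test_that("PCA score is the median of surviving replicates", {
  g <- toy_plate(list(a = c(1, 2, 10, 3), b = c(4, 5)))
  dip <- g
  dip$qc_pass <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)  # 3rd a-rep failed
  s <- collect_ppi_scores(g, dip)
  expect_equal(s$pca_score[s$prey == "a"], median(c(1, 2, 3)))
  expect_equal(s$n_replicates[s$prey == "a"], 3L)
})

test_that("pairs below the replicate minimum and border pairs are dropped", {
  g <- toy_plate(list(a = c(1, 2), b = c(3, 4)))
  dip <- g
  dip$qc_pass <- c(TRUE, FALSE, TRUE, TRUE)  # one surviving a-replicate
  s <- collect_ppi_scores(g, dip)
  expect_false("a" %in% s$prey)
  g2 <- toy_plate(list(a = c(1, 2), ctrl = c(9, 9)))
  g2$is_border[g2$prey == "ctrl"] <- TRUE
  s2 <- collect_ppi_scores(g2)
  expect_identical(s2$prey, "a")
  dip_bad <- dip
  dip_bad$row <- dip_bad$row + 100L
  expect_error(collect_ppi_scores(g, dip_bad), "misaligned")
})

test_that("quantile calling returns exactly the top fraction without ties", {
  set.seed(3)
  s <- data.frame(bait = "b", prey = paste0("p", 1:1000),
                  pca_score = sample(seq_len(1000)))
  called <- detect_interactions(s, top_quantile = 0.10)
  expect_identical(nrow(called), 100L)
  expect_true(all(called$pca_score > 900 - 1))
  expect_error(detect_interactions(s[0, ], 0.1), "empty")
})

test_that("score ratio is the log2 difference", {
  expect_identical(score_ratio(2, 2), 0)
  expect_identical(score_ratio(3, 2), 1)
  expect_identical(score_ratio(-1.5, 2.5), -4)
})

test_that("classification follows the decision table with inclusive ties", {
  wt <- data.frame(bait = "b", prey = c("lost", "weak", "ind", "strong"))
  mut <- data.frame(bait = "b", prey = c("weak", "ind", "strong", "gained"))
  ratios <- data.frame(bait = "b",
                       prey = c("lost", "weak", "ind", "strong", "none"),
                       ratio = c(-5, -3, 0, 3, 0))
  expect_message(
    cls <- classify_ppis(wt, mut, ratios, ratio_quantile = 0.26),
    "neither screen")
  get <- function(p) cls$class[cls$prey == p]
  expect_identical(get("lost"), "dependent_lost")
  expect_identical(get("gained"), "inhibited_gained")
  expect_identical(get("weak"), "dependent_weaker")
  expect_identical(get("ind"), "independent")
  # at the exact upper quantile ties classify into the extreme class
  thr <- attr(cls, "ratio_thresholds")
  expect_identical(get("strong"), "inhibited_stronger")
  expect_true(ratios$ratio[ratios$prey == "strong"] >= thr["upper"])
  # partition: every classified pair gets exactly one class
  expect_false(anyNA(cls$class))
})

test_that("planted interactions are recovered from a synthetic screen", {
  cfg <- sim_config(seed = 71, n_rows = 16, n_cols = 24, effect_log2 = 4,
                    noise_sd = 1, frac_positive = 0.1)
  sim <- gen_plate_screen(cfg, c("b1", "b2"), sprintf("p%02d", 1:40))
  normed <- lapply(split(sim$screen, sim$screen$plate_id), normalize_plate)
  scores <- collect_ppi_scores(normed,
                               split(sim$diploid, sim$diploid$plate_id))
  expect_true(all(scores$n_replicates == 4L))
  truth_key <- paste(sim$truth$planted_pairs$bait,
                     sim$truth$planted_pairs$prey)
  planted_scores <- scores$pca_score[paste(scores$bait, scores$prey)
                                     %in% truth_key]
  other_scores <- scores$pca_score[!paste(scores$bait, scores$prey)
                                   %in% truth_key]
  # planted pairs exceed the rest by about the planted effect
  expect_equal(median(planted_scores) - median(other_scores), 4,
               tolerance = 0.25)
})

test_that("growth scoring filters discordant strains and centers plates", {
  # 7 strains x 3 replicates, so one shifted strain barely moves the
  # plate median (as in a real dense plate)
  vals <- setNames(lapply(1:7, function(i) rep(i, 3)), paste0("s", 1:7))
  vals$s1 <- c(1, 2, 3)
  p1 <- toy_growth_plate(vals, "p1")
  p2 <- toy_growth_plate(vals, "p2")
  gs <- growth_scores(list(p1, p2))
  # identical plates: growth score equals the common per-strain median
  expect_equal(gs$growth_score[gs$strain == "s1"], 2)
  expect_equal(gs$growth_score[gs$strain == "s5"], 5)

  # a uniform plate offset is removed exactly by centering: corrected
  # per-plate medians agree and strain contrasts are unchanged
  p2_off <- p2
  p2_off$log2_size <- p2_off$log2_size + 1.7
  gs_off <- growth_scores(list(p1, p2_off))
  expect_equal(gs_off$median_plate1, gs_off$median_plate2)
  expect_equal(gs_off$growth_score - gs_off$growth_score[1],
               gs$growth_score - gs$growth_score[1])

  # injected inter-plate median shift of 4 leaves a corrected difference
  # beyond the cutoff of 2: the strain is removed
  p2_disc <- p2
  p2_disc$log2_size[p2_disc$strain == "s3"] <-
    p2_disc$log2_size[p2_disc$strain == "s3"] + 4
  gs_disc <- growth_scores(list(p1, p2_disc))
  expect_false("s3" %in% gs_disc$strain)
  expect_identical(attr(gs_disc, "discordant"), "s3")
  expect_true(all(paste0("s", c(1:2, 4:7)) %in% gs_disc$strain))

  expect_error(growth_scores(p1), "exactly 2")
})

test_that("plate grids round-trip through long-form TSV", {
  g <- toy_plate(list(a = c(1.25, 2.5), b = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plate_tsv(g, path)
  back <- read_plate_tsv(path)
  expect_equal(back$log2_size, g$log2_size)
  expect_identical(back$prey, g$prey)
})
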