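# Synthetic-data generators: determinism, capacity, planted structure,
# conservation invariants, round trips.

test_that("all generators are byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42, n_rows = 12, n_cols = 16)
  s1 <- gen_plate_screen(cfg, "b1", sprintf("p%02d", 1:20))
  s2 <- gen_plate_screen(cfg, "b1", sprintf("p%02d", 1:20))
  expect_identical(s1, s2)
  g1 <- gen_growth_plates(cfg, paste0("s", 1:8))
  g2 <- gen_growth_plates(cfg, paste0("s", 1:8))
  expect_identical(g1, g2)
  p <- onehot_pwm("PAPK")
  m1 <- gen_motif_dataset(p, 5, 5, 30, 0.5, seed = 7)
  m2 <- gen_motif_dataset(p, 5, 5, 30, 0.5, seed = 7)
  expect_identical(m1, m2)
  d1 <- gen_dms_counts(c("GCT", "TGG"), 500, seed = 3)
  d2 <- gen_dms_counts(c("GCT", "TGG"), 500, seed = 3)
  expect_identical(d1, d2)
  c1 <- gen_coupled_profiles(5, 6, 0.5, seed = 11)
  c2 <- gen_coupled_profiles(5, 6, 0.5, seed = 11)
  expect_identical(c1$profiles, c2$profiles)
  t1 <- gen_tracks(5, seed = 13)
  t2 <- gen_tracks(5, seed = 13)
  expect_identical(t1, t2)
  # generators leave the caller's RNG state untouched
  set.seed(99)
  before <- .Random.seed
  invisible(gen_tracks(3, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("screen generator plants effects and respects the replicate design", {
  cfg <- sim_config(seed = 3, n_rows = 12, n_cols = 16, effect_log2 = 0,
                    noise_sd = 0, plate_sd = 0, frac_positive = 0)
  sim <- gen_plate_screen(cfg, "b1", sprintf("p%02d", 1:20))
  inner <- sim$screen[!sim$screen$is_border, ]
  # degenerate noise: all values equal background + plate offset (here 0)
  expect_true(all(inner$log2_size == cfg$background_log2))
  # default design: 2 positions x 2 plates = 4 replicates per prey
  expect_true(all(table(inner$prey) == 4L))
  # border carries the control pair
  border <- sim$screen[sim$screen$is_border, ]
  expect_true(all(border$bait == "LSM8" & border$prey == "CDC39"))
  # capacity error
  expect_error(gen_plate_screen(sim_config(seed = 1, n_rows = 6, n_cols = 6),
                                "b", paste0("p", 1:100)),
               "too small")
})

test_that("growth generator yields 12 replicates and near-identical null plates", {
  cfg <- sim_config(seed = 5, n_rows = 12, n_cols = 16, plate_sd = 0,
                    noise_sd = 0.1)
  sim <- gen_growth_plates(cfg, paste0("s", 1:6))
  inner <- sim$plates[!sim$plates$is_border, ]
  expect_true(all(table(inner$strain) == 12L))
  med <- tapply(inner$log2_size, list(inner$strain, inner$plate_id), median)
  expect_lt(max(abs(med[, 1] - med[, 2])), 0.5)
  expect_error(gen_growth_plates(cfg, paste0("s", 1:200)), "too small")
})

test_that("motif generator plants exact consensus under a one-hot PWM", {
  p <- onehot_pwm("PPKPWG")
  d <- gen_motif_dataset(p, 10, 5, 40, planted_frac = 1, seed = 9)
  truth <- d$truth[d$truth$group == "dependent", ]
  for (i in seq_len(nrow(truth))) {
    s <- d$sequences[[truth$id[i]]]
    expect_identical(substr(s, truth$start0[i] + 1, truth$start0[i] + 6),
                     "PPKPWG")
  }
  expect_true(all(is.na(d$truth$start0[d$truth$group == "independent"])))
  expect_error(gen_motif_dataset(p, 1, 1, 3, 1, seed = 1), "shorter")
  expect_error(gen_motif_dataset(p, 1, 1, 30, 1.2, seed = 1), "planted_frac")
})

test_that("DMS counts conserve depth and respect planted weights", {
  eff <- data.frame(position = 1L, codon = "TGG", effect = -Inf)
  sim <- gen_dms_counts(c("GCT", "CGT"), depth = 800, effects = eff,
                        n_reps = 2, seed = 17)
  sums <- tapply(sim$counts$count, list(sim$counts$position,
                                        sim$counts$condition,
                                        sim$counts$replicate), sum)
  expect_true(all(sums == 800))
  # weight-zero variant never appears in selection
  w0 <- sim$counts[sim$counts$codon == "TGG" & sim$counts$position == 1 &
                     sim$counts$condition == "selection", ]
  expect_true(all(w0$count == 0L))
  expect_error(gen_dms_counts("GCT", effects = data.frame(
    position = 1, codon = "ZZZ", effect = 1), seed = 1), "unknown codon")
  # null case: selection frequencies track reference frequencies
  null <- gen_dms_counts("GCT", depth = 40000, n_reps = 1, seed = 23)
  byc <- split(null$counts, null$counts$condition)
  expect_equal(byc$selection$count / 40000, byc$reference$count / 40000,
               tolerance = 0.02)
})

test_that("coupled-profile generator spans the coupling extremes", {
  cp1 <- gen_coupled_profiles(7, 8, 1, seed = 3)
  h1 <- cluster_profiles(profile_distance(cp1$profiles))
  h2 <- cluster_profiles(sequence_distance(cp1$alignment))
  expect_equal(cophenetic_correlation(h1, h2), 1, tolerance = 1e-8)
  expect_identical(sort(rownames(cp1$profiles)),
                   sort(names(cp1$alignment)))
  expect_error(gen_coupled_profiles(2, 5, 0.5, seed = 1), "n_domains")
})

test_that("track generator honors the acquisition and motion settings", {
  sim <- gen_tracks(8, frame_rate = 1, duration_s = 180, seed = 3)
  expect_identical(sim$acquisition_end, 180L)
  expect_true(all(sim$tracks$frame <= 180))
  still <- gen_tracks(4, drift = 0, noise_sd = 0, disassembly_rate = 0,
                      spread_starts = FALSE, seed = 5)
  ed <- effective_distance_series(still$tracks, still$cells)
  expect_true(all(abs(ed$per_frame$mean_e) < 1e-12))
  expect_true(all(!still$truth$complete))
  # pure drift: straight tracks with linearly growing effective distance
  drifty <- gen_tracks(3, drift = 0.2, noise_sd = 0, disassembly_rate = 0,
                       spread_starts = FALSE, seed = 6)
  for (id in unique(drifty$tracks$track_id)) {
    tr <- drifty$tracks[drifty$tracks$track_id == id, ]
    expect_equal(straightness(tr), 1, tolerance = 1e-9)
  }
})

test_that("ground truth round-trips through the emitted text formats", {
  cfg <- sim_config(seed = 8, n_rows = 12, n_cols = 16)
  sim <- gen_plate_screen(cfg, "b1", sprintf("p%02d", 1:10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plate_tsv(sim$screen, path)
  expect_equal(read_plate_tsv(path)$log2_size, sim$screen$log2_size)
  p <- onehot_pwm("PAPK")
  d <- gen_motif_dataset(p, 4, 2, 25, 1, seed = 2)
  fpath <- withr::local_tempfile(fileext = ".fa")
  write_fasta(d$sequences, fpath)
  expect_identical(read_fasta(fpath), d$sequences)
})
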