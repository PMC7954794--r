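# Shared fixtures and independent oracles, all built in code.

onehot_pwm <- function(consensus, name = "onehot") {
  res <- strsplit(consensus, "")[[1L]]
  f <- matrix(0, length(res), 20L, dimnames = list(NULL, aa_alphabet()))
  f[cbind(seq_along(res), match(res, aa_alphabet()))] <- 1
  pwm(f, name = name)
}

# Dirichlet-ish random PWM; conc < 1 gives peaked columns
random_pwm <- function(k, seed, name = paste0("rand", seed), conc = 0.3) {
  set.seed(seed)
  f <- matrix(stats::rgamma(k * 20L, conc) + 1e-12, k, 20L)
  f <- f / rowSums(f)
  colnames(f) <- aa_alphabet()
  pwm(f, name = name)
}

random_seq <- function(n) paste(sample(aa_alphabet(), n, TRUE), collapse = "")

# Independent brute-force maximum-MSS oracle: plain loops, formula written
# out from scratch; enumerates every window of every PWM.
oracle_max_mss <- function(pwms, sequence) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  res <- strsplit(sequence, "")[[1L]]
  best <- -Inf
  for (p in pwms) {
    f <- p$f
    k <- nrow(f)
    info <- numeric(k)
    for (i in 1:k) for (b in 1:20) {
      if (f[i, b] > 0) info[i] <- info[i] + f[i, b] * log(20 * f[i, b])
    }
    lo <- 0
    hi <- 0
    for (i in 1:k) {
      lo <- lo + info[i] * min(f[i, ])
      hi <- hi + info[i] * max(f[i, ])
    }
    if (k > length(res)) next
    for (s in 1:(length(res) - k + 1)) {
      w <- res[s:(s + k - 1)]
      cur <- 0
      ok <- TRUE
      for (i in 1:k) {
        j <- match(w[i], colnames(f))
        if (is.na(j)) {
          ok <- FALSE
          break
        }
        cur <- cur + info[i] * f[i, j]
      }
      if (ok && (cur - lo) / (hi - lo) > best) {
        best <- unname((cur - lo) / (hi - lo))
      }
    }
  }
  best
}

# Long-form plate from named list prey -> replicate values (one column of
# positions, no border)
toy_plate <- function(values_by_prey, plate_id = "p1", bait = "b",
                      qc = NULL) {
  prey <- rep(names(values_by_prey), lengths(values_by_prey))
  v <- unlist(values_by_prey, use.names = FALSE)
  n <- length(v)
  data.frame(plate_id = plate_id, row = seq_len(n), col = 1L, bait = bait,
             prey = prey, is_border = FALSE, log2_size = v,
             qc_pass = if (is.null(qc)) rep(TRUE, n) else qc,
             stringsAsFactors = FALSE)
}

toy_growth_plate <- function(values_by_strain, plate_id = "p1",
                             condition = "c1") {
  strain <- rep(names(values_by_strain), lengths(values_by_strain))
  v <- unlist(values_by_strain, use.names = FALSE)
  n <- length(v)
  data.frame(plate_id = plate_id, condition = condition,
             row = seq_len(n), col = 1L, strain = strain,
             is_border = FALSE, log2_size = v, qc_pass = TRUE,
             stringsAsFactors = FALSE)
}

toy_track <- function(xy, id = "t1", cell = "c1",
                      frames = seq_len(nrow(xy))) {
  data.frame(track_id = id, cell_id = cell, frame = frames,
             x = xy[, 1L], y = xy[, 2L], stringsAsFactors = FALSE)
}

toy_cells <- function(cell = "c1", cx = 0, cy = 0) {
  data.frame(cell_id = cell, centroid_x = cx, centroid_y = cy,
             stringsAsFactors = FALSE)
}

# build a count-table pair -> ratios for one replicate
ratios_from_counts <- function(counts, rep_id, pseudocount = 0.5) {
  sel <- variant_frequencies(
    counts[counts$condition == "selection" & counts$replicate == rep_id, ],
    pseudocount)
  ref <- variant_frequencies(
    counts[counts$condition == "reference" & counts$replicate == rep_id, ],
    pseudocount)
  variant_log_ratios(sel, ref, pseudocount)
}

dms_scores_from_counts <- function(counts, pseudocount = 0.5) {
  reps <- sort(unique(counts$replicate))
  dms_scores(lapply(reps, function(r) ratios_from_counts(counts, r,
                                                         pseudocount)))
}
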