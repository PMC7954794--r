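# Position weight matrices and MATCH-style matrix similarity scoring (MSS),
# with the two permutation nulls used to test motif enrichment: random
# peptides drawn from background residue frequencies, and random
# reassignment of PWMs to domains.

#' Construct a position weight matrix
#'
#' A PWM is a k x 20 matrix of residue frequencies, one row per motif
#' position, columns ordered as [aa_alphabet()]. Each row must sum to 1.
#' The information vector weighting each position is computed on
#' construction.
#'
#' @param f Numeric k x 20 frequency matrix. Columns may be named with
#'   one-letter residue codes in any order; unnamed matrices are assumed to
#'   follow [aa_alphabet()] order.
#' @param name Matrix identifier.
#' @param sh3_id Optional identifier of the domain the PWM belongs to.
#' @return An object of class \code{"pwm"} with elements \code{name},
#'   \code{sh3_id}, \code{f} and \code{info}.
#' @export
pwm <- function(f, name = "pwm", sh3_id = NULL) {
  f <- as.matrix(f)
  aa <- aa_alphabet()
  if (!is.null(colnames(f))) {
    if (!setequal(colnames(f), aa)) {
      stop("PWM columns must be the 20 standard one-letter residue codes")
    }
    f <- f[, aa, drop = FALSE]
  } else {
    if (ncol(f) != 20L) stop("PWM must have 20 residue columns")
    colnames(f) <- aa
  }
  if (any(f < 0)) stop("negative frequency in PWM")
  if (any(abs(rowSums(f) - 1) > 1e-9)) {
    stop("each PWM position must sum to 1 (tolerance 1e-9)")
  }
  info <- information_vector(f)
  if (all(info <= 0)) stop("PWM has no informative position")
  structure(list(name = name, sh3_id = sh3_id, f = f, info = info),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM '", x$name, "'", if (!is.null(x$sh3_id)) paste0(" (", x$sh3_id, ")"),
      ": ", nrow(x$f), " positions, total information ",
      signif(sum(x$info), 4), " nats\n", sep = "")
  invisible(x)
}

#' MATCH information vector of a frequency matrix
#'
#' Position weights I(i) = sum_b f(i,b) ln(20 f(i,b)), with 0 ln 0 := 0 —
#' the MATCH information weighting generalized from the 4-letter nucleotide
#' alphabet to the 20-letter amino-acid alphabet. A one-hot position scores
#' ln 20; a uniform position scores 0.
#'
#' @param f k x 20 row-stochastic frequency matrix.
#' @return Numeric vector of length k.
#' @export
information_vector <- function(f) {
  f <- as.matrix(f)
  if (any(f < 0)) stop("negative frequency")
  term <- f * log(20 * f)
  term[f == 0] <- 0
  rowSums(term)
}

# residue -> column index in aa_alphabet order; NA for non-standard residues
residue_index <- function(residues) {
  match(residues, aa_alphabet())
}

#' Matrix similarity score of one window
#'
#' MSS = (sum_i I(i) f(i, a_i) - Min) / (Max - Min) with
#' Min = sum_i I(i) min_b f(i,b) and Max = sum_i I(i) max_b f(i,b),
#' so a window matching the most frequent residue at every informative
#' position scores exactly 1 and the all-worst window scores 0.
#'
#' @param pwm A [pwm()] object.
#' @param window Peptide of length equal to the PWM width.
#' @return Score in \[0, 1\].
#' @export
mss_window <- function(pwm, window) {
  res <- as_residues(window)
  k <- nrow(pwm$f)
  if (length(res) != k) {
    stop("window length ", length(res), " != PWM width ", k)
  }
  idx <- residue_index(res)
  if (anyNA(idx)) stop("window contains non-standard residues")
  lo <- sum(pwm$info * apply(pwm$f, 1L, min))
  hi <- sum(pwm$info * apply(pwm$f, 1L, max))
  if (hi - lo <= 0) stop("degenerate PWM: all positions uninformative")
  cur <- sum(pwm$info * pwm$f[cbind(seq_len(k), idx)])
  (cur - lo) / (hi - lo)
}

# all window scores of one PWM along a sequence; NA where a window covers a
# non-standard residue; numeric(0) when the sequence is shorter than the PWM
mss_scan <- function(pwm, sequence) {
  res <- as_residues(sequence)
  k <- nrow(pwm$f)
  n <- length(res) - k + 1L
  if (n < 1L) return(numeric(0L))
  idx <- residue_index(res)
  info <- pwm$info
  lo <- sum(info * apply(pwm$f, 1L, min))
  hi <- sum(info * apply(pwm$f, 1L, max))
  if (hi - lo <= 0) stop("degenerate PWM: all positions uninformative")
  contrib <- matrix(0, nrow = k, ncol = n)
  for (i in seq_len(k)) {
    ii <- idx[seq.int(i, i + n - 1L)]
    contrib[i, ] <- info[i] * pwm$f[i, ][ii]  # NA propagates for bad residues
  }
  (colSums(contrib) - lo) / (hi - lo)
}

#' Maximum MSS of a sequence against a domain's PWM set
#'
#' Scores every k-mer window of the sequence against every PWM assigned to
#' the domain and returns the overall maximum (Max. MSS). Windows containing
#' non-standard residues are skipped; the first-occurring window (and the
#' earlier PWM in list order) wins ties. PWMs wider than the sequence are
#' skipped; if the sequence is shorter than every PWM an error is raised.
#'
#' @param pwms A [pwm()] object or list of them (multiple specificities of
#'   one domain).
#' @param sequence Protein sequence (string or residue vector).
#' @param sequence_id Identifier copied into the result.
#' @return One-row data frame: \code{sequence_id}, \code{pwm_name},
#'   \code{max_mss}, \code{window_start} (0-based), \code{window_seq}.
#' @export
max_mss <- function(pwms, sequence, sequence_id = "seq") {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  stopifnot(length(pwms) >= 1L)
  res <- as_residues(sequence)
  widths <- vapply(pwms, function(p) nrow(p$f), integer(1L))
  if (length(res) < min(widths)) {
    stop("sequence length ", length(res), " shorter than every PWM (min width ",
         min(widths), ")")
  }
  best <- list(score = -Inf, pwm = NA_character_, start = NA_integer_, k = NA)
  for (p in pwms) {
    sc <- mss_scan(p, res)
    if (length(sc) == 0L || all(is.na(sc))) next
    j <- which.max(sc)  # first occurrence wins ties; NAs never selected
    if (sc[j] > best$score) {
      best <- list(score = sc[j], pwm = p$name, start = j - 1L,
                   k = nrow(p$f))
    }
  }
  if (!is.finite(best$score)) stop("no scoreable window in sequence")
  data.frame(sequence_id = sequence_id, pwm_name = best$pwm,
             max_mss = best$score, window_start = best$start,
             window_seq = paste(res[seq.int(best$start + 1L,
                                            best$start + best$k)],
                                collapse = ""),
             stringsAsFactors = FALSE)
}

#' Maximum MSS for a set of sequences
#'
#' @param pwms PWM or list of PWMs for one domain.
#' @param sequences Named character vector (or list) of protein sequences.
#' @return Data frame, one row per sequence (see [max_mss()]).
#' @export
max_mss_set <- function(pwms, sequences) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  out <- mapply(function(s, id) max_mss(pwms, s, id),
                sequences, ids, SIMPLIFY = FALSE)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Random-peptide null distribution of maximum MSS
#'
#' Draws n random peptides i.i.d. from a background residue-frequency table
#' (lengths resampled from an empirical length pool, e.g. the analyzed prey
#' set) and records their maximum MSS against the given PWM set. The 95th
#' empirical percentile of the null is the conventional high-MSS threshold.
#'
#' @param pwms PWM or list of PWMs.
#' @param background Named numeric vector of residue frequencies summing
#'   to 1 (defaults to uniform).
#' @param lengths Integer vector to resample peptide lengths from (a single
#'   value gives fixed-length peptides).
#' @param n Number of random peptides (default 10,000).
#' @param seed Integer RNG seed.
#' @return Object of class \code{"mss_null"}: \code{kind}, \code{samples},
#'   \code{threshold_95}, \code{n}, \code{seed}.
#' @export
random_peptide_null <- function(pwms, background = NULL, lengths = 100L,
                                n = 10000L, seed = 1L) {
  stopifnot(n >= 1L, all(lengths >= 1L))
  aa <- aa_alphabet()
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), aa)
  }
  if (!setequal(names(background), aa) || any(background < 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be named residue frequencies summing to 1")
  }
  background <- background[aa]
  rng <- local_rng(seed)
  lens <- if (length(lengths) == 1L) rep.int(lengths, n) else
    sample(lengths, n, replace = TRUE)
  samples <- vapply(lens, function(L) {
    s <- sample(aa, L, replace = TRUE, prob = background)
    max_mss(pwms, s)$max_mss
  }, numeric(1L))
  restore_rng(rng)
  structure(list(kind = "random_peptides", samples = samples,
                 threshold_95 = stats::quantile(samples, 0.95, names = FALSE),
                 n = n, seed = seed),
            class = "mss_null")
}

#' @export
print.mss_null <- function(x, ...) {
  cat("MSS null (", x$kind, "): n = ", x$n, ", 95th percentile = ",
      signif(x$threshold_95, 4), "\n", sep = "")
  invisible(x)
}

#' PWM-reassignment permutation test
#'
#' Observed statistic: the pooled maximum MSS of each domain's dependent
#' preys scored against that domain's own PWMs. Null: the domain-to-PWM
#' assignment is randomly permuted (derangements not enforced) and the
#' pooled scores recomputed, repeating rounds until at least \code{n_perm}
#' null scores are accumulated. The two samples are compared with a
#' two-tailed Mann-Whitney rank test.
#'
#' @param domain_to_preys Named list: domain -> named character vector of
#'   prey sequences.
#' @param domain_to_pwms Named list: domain -> [pwm()] or list of PWMs.
#'   Domains missing a PWM are excluded with a message.
#' @param n_perm Minimum number of permuted max-MSS samples (default 10,000).
#' @param seed Integer RNG seed.
#' @return List with \code{observed}, \code{permuted}, \code{p},
#'   \code{n_rounds} and \code{seed}.
#' @export
pwm_reassignment_test <- function(domain_to_preys, domain_to_pwms,
                                  n_perm = 10000L, seed = 1L) {
  doms <- intersect(names(domain_to_preys), names(domain_to_pwms))
  dropped <- setdiff(names(domain_to_preys), doms)
  if (length(dropped) > 0L) {
    message("excluding domain(s) without PWMs: ", paste(dropped, collapse = ", "))
  }
  if (length(doms) < 2L) stop("need at least two domains with PWMs to permute")
  # precompute every prey-set x PWM-set pooled score vector once
  score_cache <- matrix(vector("list", length(doms)^2), length(doms),
                        dimnames = list(doms, doms))
  for (d in doms) {
    for (p in doms) {
      score_cache[[d, p]] <-
        max_mss_set(domain_to_pwms[[p]], domain_to_preys[[d]])$max_mss
    }
  }
  observed <- unlist(lapply(doms, function(d) score_cache[[d, d]]),
                     use.names = FALSE)
  rng <- local_rng(seed)
  permuted <- list()
  total <- 0L
  rounds <- 0L
  while (total < n_perm) {
    perm <- sample(doms)
    rounds <- rounds + 1L
    sc <- unlist(lapply(seq_along(doms), function(i) {
      score_cache[[doms[i], perm[i]]]
    }), use.names = FALSE)
    permuted[[rounds]] <- sc
    total <- total + length(sc)
  }
  restore_rng(rng)
  permuted <- unlist(permuted, use.names = FALSE)
  p <- stats::wilcox.test(observed, permuted, alternative = "two.sided",
                          exact = FALSE)$p.value
  list(observed = observed, permuted = permuted, p = p,
       n_rounds = rounds, seed = seed)
}

#' Rank-test enrichment of one max-MSS group over another
#'
#' Mann-Whitney comparison of two groups of maximum MSS values (e.g.
#' SH3-dependent vs SH3-independent preys), optionally also reporting the
#' fraction of each group at or above a high-MSS threshold such as the
#' random-peptide 95th percentile.
#'
#' @param scores_a,scores_b Numeric score vectors (a is the putatively
#'   enriched group).
#' @param alternative \code{"greater"} (a right-shifted relative to b) or
#'   \code{"two_sided"}.
#' @param threshold Optional high-score threshold.
#' @return List with \code{p}, and when a threshold is given
#'   \code{frac_a_above} and \code{frac_b_above}.
#' @export
enrichment_test <- function(scores_a, scores_b,
                            alternative = c("greater", "two_sided"),
                            threshold = NULL) {
  alternative <- match.arg(alternative)
  if (length(scores_a) == 0L || length(scores_b) == 0L) stop("empty group")
  alt <- if (alternative == "greater") "greater" else "two.sided"
  p <- stats::wilcox.test(scores_a, scores_b, alternative = alt,
                          exact = FALSE)$p.value
  out <- list(p = p)
  if (!is.null(threshold)) {
    out$frac_a_above <- mean(scores_a >= threshold)
    out$frac_b_above <- mean(scores_b >= threshold)
  }
  out
}

#' Read PWMs from a tab-delimited multi-matrix file
#'
#' Format: records introduced by \code{>name} (optionally
#' \code{>name<TAB>sh3_id}), followed by a header line of the 20 one-letter
#' residue codes and one tab-separated frequency row per motif position.
#'
#' @param path File path.
#' @return Named list of [pwm()] objects.
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no '>' records in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    head_fields <- strsplit(sub("^>", "", lines[starts[i]]), "\t")[[1L]]
    name <- head_fields[1L]
    sh3 <- if (length(head_fields) > 1L) head_fields[2L] else NULL
    block <- lines[(starts[i] + 1L):ends[i]]
    header <- strsplit(block[1L], "\t")[[1L]]
    rows <- do.call(rbind, lapply(block[-1L], function(l) {
      as.numeric(strsplit(l, "\t")[[1L]])
    }))
    colnames(rows) <- header
    out[[name]] <- pwm(rows, name = name, sh3_id = sh3)
  }
  out
}

#' Write PWMs in the tab-delimited multi-matrix format
#'
#' @param pwms List of [pwm()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    hdr <- if (is.null(p$sh3_id)) paste0(">", p$name) else
      paste0(">", p$name, "\t", p$sh3_id)
    writeLines(hdr, con)
    writeLines(paste(colnames(p$f), collapse = "\t"), con)
    utils::write.table(p$f, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
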