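# Seeded synthetic-data generators. Each generator emulates the statistical
# structure of one experimental input (colony plates, motif-bearing
# sequence sets, DMS count tables, coupled profile/sequence sets, inward-
# drifting foci tracks) with a known ground truth, so every analysis stage
# is testable without external data. All generators take an explicit seed
# and never touch the caller's RNG state.

#' Simulation configuration for plate-based generators
#'
#' Colony sizes are simulated directly in log2 space: value = plate
#' background + per-plate offset + planted effect + Gaussian replicate
#' noise.
#'
#' @param seed Integer RNG seed.
#' @param n_rows,n_cols Plate dimensions (default 32 x 48, a 1536 array).
#' @param border_width Rows/columns of control-strain border (default 2).
#' @param background_log2 Plate background level in log2 units (default 10).
#' @param plate_sd Between-plate offset standard deviation (default 0.25).
#' @param noise_sd Replicate noise standard deviation (default 1).
#' @param effect_log2 Planted interaction effect in log2 units (default 4).
#' @param frac_positive Fraction of bait-prey pairs with a planted
#'   interaction (default 0.1).
#' @return Object of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L, n_rows = 32L, n_cols = 48L,
                       border_width = 2L, background_log2 = 10,
                       plate_sd = 0.25, noise_sd = 1, effect_log2 = 4,
                       frac_positive = 0.1) {
  stopifnot(border_width >= 0L, frac_positive >= 0, frac_positive <= 1,
            n_rows > 2L * border_width, n_cols > 2L * border_width,
            plate_sd >= 0, noise_sd >= 0)
  structure(list(seed = as.integer(seed), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 border_width = as.integer(border_width),
                 background_log2 = background_log2, plate_sd = plate_sd,
                 noise_sd = noise_sd, effect_log2 = effect_log2,
                 frac_positive = frac_positive),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_rows, "x", x$n_cols, " plate, border ",
      x$border_width, ", effect ", x$effect_log2, " log2, noise sd ",
      x$noise_sd, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# coordinates of the border frame and of the inner array
plate_layout <- function(cfg) {
  rows <- seq_len(cfg$n_rows)
  cols <- seq_len(cfg$n_cols)
  grid <- expand.grid(row = rows, col = cols)
  bw <- cfg$border_width
  grid$is_border <- grid$row <= bw | grid$row > cfg$n_rows - bw |
    grid$col <= bw | grid$col > cfg$n_cols - bw
  grid
}

# place each prey at n_copies random inner positions, duplicates never
# adjacent (8-neighborhood); bounded redraws
place_preys <- function(inner, preys, n_copies) {
  need <- length(preys) * n_copies
  if (need > nrow(inner)) {
    stop("grid too small: ", need, " prey positions needed, ",
         nrow(inner), " available")
  }
  for (attempt in 1:50) {
    slots <- sample.int(nrow(inner), need)
    assign <- rep(seq_along(preys), each = n_copies)
    ok <- TRUE
    for (p in seq_along(preys)) {
      pos <- inner[slots[assign == p], , drop = FALSE]
      if (n_copies >= 2L) {
        dd <- as.matrix(stats::dist(pos[, c("row", "col")]))
        if (any(dd[upper.tri(dd)] < 1.5)) { ok <- FALSE; break }
      }
    }
    if (ok) {
      return(data.frame(inner[slots, c("row", "col")],
                        prey = preys[assign], stringsAsFactors = FALSE))
    }
  }
  stop("could not place preys without adjacent duplicates")
}

#' Generate a synthetic DHFR-PCA screen
#'
#' Per bait, \code{n_plates} plates are produced with each prey present in
#' \code{n_prey_positions} randomized, non-adjacent duplicate positions
#' (the default 2 positions x 2 plates gives 4 replicates per pair). A
#' border frame of control-pair positions surrounds the array. Colony
#' log2 sizes are background + plate offset + planted effect + noise.
#'
#' @param cfg A [sim_config()].
#' @param baits,preys Character vectors of strain names.
#' @param n_prey_positions Duplicate positions per prey per plate.
#' @param n_plates Plates per bait.
#' @param planted Optional data frame \code{bait}, \code{prey},
#'   \code{effect} fixing the planted interactions; by default
#'   \code{frac_positive} of all pairs are planted with
#'   \code{effect_log2}.
#' @param diploid_dropout Probability that a replicate colony failed the
#'   diploid selection (marked \code{qc_pass = FALSE} in the diploid grid).
#' @return List: \code{screen} (plate grid), \code{diploid} (aligned
#'   diploid-selection grid), \code{truth} (planted pairs and plate
#'   offsets).
#' @export
gen_plate_screen <- function(cfg, baits, preys, n_prey_positions = 2L,
                             n_plates = 2L, planted = NULL,
                             diploid_dropout = 0) {
  layout <- plate_layout(cfg)
  inner <- layout[!layout$is_border, , drop = FALSE]
  rng <- local_rng(cfg$seed)
  on.exit(restore_rng(rng))
  if (is.null(planted)) {
    pairs <- expand.grid(bait = baits, prey = preys,
                         stringsAsFactors = FALSE)
    n_pos <- round(cfg$frac_positive * nrow(pairs))
    idx <- sample.int(nrow(pairs), n_pos)
    planted <- data.frame(pairs[idx, , drop = FALSE],
                          effect = rep(cfg$effect_log2, n_pos),
                          row.names = NULL)
  }
  pkey <- paste(planted$bait, planted$prey, sep = "\r")
  screen <- list()
  diploid <- list()
  offsets <- list()
  for (b in baits) {
    for (pl in seq_len(n_plates)) {
      plate_id <- paste0(b, "_plate", pl)
      offset <- stats::rnorm(1L, 0, cfg$plate_sd)
      placement <- place_preys(inner, preys, n_prey_positions)
      g <- layout
      g$plate_id <- plate_id
      g$bait <- ifelse(g$is_border, "LSM8", b)
      g$prey <- NA_character_
      g$prey[g$is_border] <- "CDC39"
      m <- match(paste(g$row, g$col), paste(placement$row, placement$col))
      g$prey[!is.na(m)] <- placement$prey[m[!is.na(m)]]
      g <- g[!is.na(g$prey), , drop = FALSE]
      eff <- planted$effect[match(paste(g$bait, g$prey, sep = "\r"), pkey)]
      eff[is.na(eff) | g$is_border] <- 0
      g$log2_size <- cfg$background_log2 + offset + eff +
        stats::rnorm(nrow(g), 0, cfg$noise_sd)
      g$qc_pass <- TRUE
      d <- g
      d$qc_pass <- stats::runif(nrow(d)) >= diploid_dropout
      cols <- c("plate_id", "row", "col", "bait", "prey", "is_border",
                "log2_size", "qc_pass")
      screen[[plate_id]] <- g[, cols]
      diploid[[plate_id]] <- d[, cols]
      offsets[[plate_id]] <- offset
    }
  }
  list(screen = do.call(rbind, c(unname(screen),
                                 list(make.row.names = FALSE))),
       diploid = do.call(rbind, c(unname(diploid),
                                  list(make.row.names = FALSE))),
       truth = list(planted_pairs = planted,
                    plate_offsets = unlist(offsets)))
}

#' Generate synthetic stress-condition growth plates
#'
#' Two plate replicates per condition, each strain at
#' \code{n_replicates} random inner positions per plate (default 6, for 12
#' replicates in total). Strains listed in \code{discordant} receive an
#' extra shift on the second plate larger than the discordance cutoff.
#'
#' @param cfg A [sim_config()].
#' @param strains Character vector of strain names.
#' @param condition Condition label.
#' @param discordant Strains given an inter-plate median shift.
#' @param n_replicates Replicate positions per strain per plate.
#' @param n_plates Plate replicates per condition (the scoring step
#'   requires 2).
#' @param discordant_shift Log2 shift applied to discordant strains on the
#'   second plate (default 3, beyond the cutoff of 2).
#' @param strain_sd Standard deviation of per-strain growth baselines.
#' @param timepoint_h Timepoint label attached to the plates.
#' @return List: \code{plates} (plate grid with \code{strain} and
#'   \code{condition} columns), \code{truth} (strain baselines, plate
#'   offsets, discordant set).
#' @export
gen_growth_plates <- function(cfg, strains, condition = "stress1",
                              discordant = character(), n_replicates = 6L,
                              n_plates = 2L, discordant_shift = 3,
                              strain_sd = 1, timepoint_h = 74) {
  layout <- plate_layout(cfg)
  inner <- layout[!layout$is_border, , drop = FALSE]
  if (length(strains) * n_replicates > nrow(inner)) {
    stop("grid too small: ", length(strains) * n_replicates,
         " strain positions needed, ", nrow(inner), " available")
  }
  rng <- local_rng(cfg$seed)
  on.exit(restore_rng(rng))
  baseline <- stats::setNames(stats::rnorm(length(strains), 0, strain_sd),
                              strains)
  plates <- list()
  offsets <- numeric(n_plates)
  for (pl in seq_len(n_plates)) {
    plate_id <- paste0(condition, "_plate", pl)
    offsets[pl] <- stats::rnorm(1L, 0, cfg$plate_sd)
    slots <- sample.int(nrow(inner), length(strains) * n_replicates)
    g <- layout
    g$plate_id <- plate_id
    g$condition <- condition
    g$timepoint <- timepoint_h
    g$strain <- NA_character_
    g$strain[g$is_border] <- "BY4741"
    assign <- rep(strains, each = n_replicates)
    g$strain[!g$is_border][slots] <- assign
    g <- g[!is.na(g$strain), , drop = FALSE]
    shift <- ifelse(pl == 2L & g$strain %in% discordant, discordant_shift, 0)
    base <- ifelse(g$is_border, 0, baseline[g$strain])
    g$log2_size <- cfg$background_log2 + offsets[pl] + base + shift +
      stats::rnorm(nrow(g), 0, cfg$noise_sd)
    g$qc_pass <- TRUE
    plates[[plate_id]] <- g[, c("plate_id", "condition", "timepoint", "row",
                                "col", "strain", "is_border", "log2_size",
                                "qc_pass")]
  }
  list(plates = do.call(rbind, c(unname(plates),
                                 list(make.row.names = FALSE))),
       truth = list(baseline = baseline, plate_offsets = offsets,
                    discordant = discordant))
}

#' Generate sequence sets with planted PWM motifs
#'
#' "Dependent" sequences contain, with probability \code{planted_frac}, a
#' window sampled column-wise from an assigned PWM at a recorded position;
#' all other residues are drawn from the background frequencies.
#' "Independent" sequences are pure background.
#'
#' @param pwms A [pwm()] or list of PWMs; dependent sequences are assigned
#'   PWMs in rotation.
#' @param n_dep,n_indep Group sizes.
#' @param length Sequence length (>= the widest PWM).
#' @param planted_frac Planting probability in \[0, 1\].
#' @param background Named residue frequencies (default uniform).
#' @param seed Integer RNG seed.
#' @return List: \code{sequences} (named character vector,
#'   \code{dep_*}/\code{indep_*}), \code{truth} (data frame \code{id},
#'   \code{group}, \code{pwm_name}, \code{start0}: 0-based planted window
#'   start, NA when unplanted).
#' @export
gen_motif_dataset <- function(pwms, n_dep, n_indep, length = 100L,
                              planted_frac = 1, background = NULL,
                              seed = 1L) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  stopifnot(planted_frac >= 0, planted_frac <= 1)
  widths <- vapply(pwms, function(p) nrow(p$f), integer(1L))
  if (length < max(widths)) stop("sequence length shorter than widest PWM")
  aa <- aa_alphabet()
  if (is.null(background)) background <- stats::setNames(rep(1 / 20, 20), aa)
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  background <- background[aa]
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  draw_bg <- function(n) paste(sample(aa, n, TRUE, background), collapse = "")
  seqs <- character(0L)
  truth <- list()
  for (i in seq_len(n_dep)) {
    id <- paste0("dep_", i)
    p <- pwms[[(i - 1L) %% length(pwms) + 1L]]
    s <- draw_bg(length)
    start0 <- NA_integer_
    if (stats::runif(1L) < planted_frac) {
      k <- nrow(p$f)
      start0 <- sample.int(length - k + 1L, 1L) - 1L
      motif <- vapply(seq_len(k), function(j) {
        sample(aa, 1L, prob = p$f[j, ])
      }, character(1L))
      substr(s, start0 + 1L, start0 + k) <- paste(motif, collapse = "")
    }
    seqs[id] <- s
    truth[[id]] <- data.frame(id = id, group = "dependent",
                              pwm_name = p$name, start0 = start0,
                              stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_indep)) {
    id <- paste0("indep_", i)
    seqs[id] <- draw_bg(length)
    truth[[id]] <- data.frame(id = id, group = "independent",
                              pwm_name = NA_character_,
                              start0 = NA_integer_, stringsAsFactors = FALSE)
  }
  list(sequences = seqs,
       truth = do.call(rbind, c(unname(truth), list(make.row.names = FALSE))))
}

#' Generate DMS count tables with known fitness effects
#'
#' Emulates NNN saturation libraries: at every wild-type codon position the
#' 64 codons are present; reference counts are multinomial over the
#' variants at that position, selection counts are multinomial with weights
#' proportional to reference frequency x 2^effect. Depths are exact by
#' construction (counts sum to \code{depth} per position per condition).
#'
#' @param wt_codons Character vector of wild-type codons (the positions).
#' @param depth Reads per position per condition.
#' @param effects Optional data frame \code{position}, \code{codon},
#'   \code{effect} (log2 fitness effects); unlisted variants — including
#'   all synonymous codons — default to 0. \code{-Inf} gives weight 0.
#' @param n_reps Number of biological replicates (default 2).
#' @param seed Integer RNG seed.
#' @return List: \code{counts} (long count table over conditions
#'   reference/selection and replicates), \code{truth} (the effect map).
#' @export
gen_dms_counts <- function(wt_codons, depth = 5000L, effects = NULL,
                           n_reps = 2L, seed = 1L) {
  stopifnot(depth > 0)
  codons <- names(genetic_code())
  bad <- setdiff(wt_codons, codons)
  if (length(bad) > 0L) stop("unknown wild-type codon(s): ",
                             paste(bad, collapse = ", "))
  n_pos <- length(wt_codons)
  eff <- matrix(0, nrow = n_pos, ncol = 64L,
                dimnames = list(NULL, codons))
  if (!is.null(effects)) {
    if (!all(effects$codon %in% codons)) {
      stop("unknown codon in effects: ",
           paste(setdiff(effects$codon, codons), collapse = ", "))
    }
    stopifnot(all(effects$position >= 1), all(effects$position <= n_pos))
    eff[cbind(effects$position, match(effects$codon, codons))] <-
      effects$effect
  }
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  out <- list()
  for (rep_i in seq_len(n_reps)) {
    for (pos in seq_len(n_pos)) {
      ref_p <- rep(1 / 64, 64L)
      ref_counts <- as.integer(stats::rmultinom(1L, depth, ref_p))
      w <- ref_p * 2^eff[pos, ]
      if (sum(w) <= 0) stop("all selection weights zero at position ", pos)
      sel_counts <- as.integer(stats::rmultinom(1L, depth, w / sum(w)))
      out[[length(out) + 1L]] <- data.frame(
        condition = rep(c("reference", "selection"), each = 64L),
        replicate = rep_i,
        position = pos,
        codon = rep(codons, 2L),
        count = c(ref_counts, sel_counts),
        depth = depth,
        wt_codon = wt_codons[pos],
        stringsAsFactors = FALSE)
    }
  }
  truth <- data.frame(position = rep(seq_len(n_pos), each = 64L),
                      codon = rep(codons, n_pos),
                      effect = as.numeric(t(eff)),
                      stringsAsFactors = FALSE)
  list(counts = do.call(rbind, c(out, list(make.row.names = FALSE))),
       truth = truth)
}

# evolve one fixed-length protein sequence set along a tree: per branch,
# each site substitutes with probability 1 - exp(-rate * length), new
# residue uniform over the other 19
evolve_sequences <- function(tree, seq_length, rate) {
  aa <- aa_alphabet()
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- sample(aa, seq_length, replace = TRUE)
  tr <- stats::reorder(tree, "cladewise")
  edges <- tr$edge
  lens <- tr$edge.length
  for (i in seq_len(nrow(edges))) {
    parent <- edges[i, 1L]
    child <- edges[i, 2L]
    s <- seqs[[parent]]
    p_mut <- 1 - exp(-rate * lens[i])
    hit <- stats::runif(seq_length) < p_mut
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(r) sample(setdiff(aa, r), 1L),
                       character(1L))
    }
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                character(1L))
  stats::setNames(out, tree$tip.label)
}

#' Generate coupled interaction profiles and domain sequences
#'
#' Domain sequences are evolved along a random tree; an exact Euclidean
#' embedding of their identity-distance matrix (classical MDS with Cailliez
#' correction) provides profile coordinates, which are mixed with Gaussian
#' noise: profile = coupling x embedding + (1 - coupling) x noise. At
#' coupling 1 the profile dendrogram reproduces the sequence dendrogram
#' (cophenetic correlation 1, since the embedding shifts all pairwise
#' distances by a constant); at coupling 0 profiles are independent of the
#' sequences.
#'
#' @param n_domains Number of domains (>= 3).
#' @param n_preys Profile dimension (columns).
#' @param coupling Mixing weight in \[0, 1\].
#' @param seed Integer RNG seed.
#' @param seq_length Domain sequence length (default 60, SH3-sized).
#' @param rate Substitution rate per unit branch length.
#' @return List: \code{profiles} (n_domains x n_preys matrix),
#'   \code{alignment} (named sequences, equal length), \code{tree}
#'   (the generating phylogeny), \code{coupling}.
#' @export
gen_coupled_profiles <- function(n_domains, n_preys, coupling, seed = 1L,
                                 seq_length = 60L, rate = 0.5) {
  stopifnot(n_domains >= 3L, coupling >= 0, coupling <= 1, n_preys >= 1L)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  tree <- ape::rtree(n_domains)
  aln <- evolve_sequences(tree, seq_length, rate)
  dseq <- sequence_distance(aln)
  # full-rank Cailliez-corrected classical MDS reproduces the (corrected)
  # distances exactly; the trailing zero-eigenvalue warning is expected
  emb <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dseq), k = n_domains - 1L,
                    add = TRUE)$points)
  if (ncol(emb) > n_preys) {
    warning("n_preys < n_domains - 1: embedding truncated, coupling-1 ",
            "reproduction is approximate")
    emb <- emb[, seq_len(n_preys), drop = FALSE]
  } else if (ncol(emb) < n_preys) {
    emb <- cbind(emb, matrix(0, n_domains, n_preys - ncol(emb)))
  }
  scale <- stats::sd(as.numeric(emb))
  if (!is.finite(scale) || scale == 0) scale <- 1
  noise <- matrix(stats::rnorm(n_domains * n_preys, 0, scale),
                  n_domains, n_preys)
  profiles <- coupling * emb + (1 - coupling) * noise
  rownames(profiles) <- tree$tip.label
  colnames(profiles) <- paste0("prey", seq_len(n_preys))
  list(profiles = profiles, alignment = aln, tree = tree,
       coupling = coupling)
}

#' Generate inward-drifting particle tracks with stochastic disassembly
#'
#' Each track starts near its cell boundary and moves toward the cell
#' centroid at \code{drift} px/frame with isotropic Gaussian noise; it
#' terminates at a geometric (memoryless per-frame hazard) disassembly
#' time. Tracks truncated by the end of the acquisition are flagged
#' incomplete. Optionally, a fraction of tracks get a spurious outward
#' tail (for testing trajectory trimming).
#'
#' @param n_tracks Number of tracks.
#' @param frame_rate Frames per second (default 1).
#' @param duration_s Acquisition length in seconds (default 180, i.e.
#'   3 min at 1 frame/s).
#' @param drift Inward speed in px/frame.
#' @param noise_sd Positional noise sd in px/frame.
#' @param disassembly_rate Per-frame disassembly hazard (0 = never).
#' @param seed Integer RNG seed.
#' @param r0_range Start radius range (px) from the centroid.
#' @param spread_starts Whether track start frames are spread uniformly
#'   over the acquisition (otherwise all start at frame 1).
#' @param outward_frac Fraction of tracks given a spurious outward tail.
#' @param outward_len Tail length in frames.
#' @param outward_drift Outward speed of the tail in px/frame.
#' @return List: \code{tracks} (long track table), \code{cells}
#'   (centroids), \code{truth} (per-track start/end frames, completeness,
#'   tail start).
#' @export
gen_tracks <- function(n_tracks = 50L, frame_rate = 1, duration_s = 180,
                       drift = 0.15, noise_sd = 0.05,
                       disassembly_rate = 0.02, seed = 1L,
                       r0_range = c(8, 12), spread_starts = TRUE,
                       outward_frac = 0, outward_len = 8L,
                       outward_drift = 2.5) {
  stopifnot(duration_s > 0, frame_rate > 0)
  total_frames <- as.integer(round(frame_rate * duration_s))
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  tracks <- list()
  cells <- list()
  truth <- list()
  for (i in seq_len(n_tracks)) {
    tid <- sprintf("track%03d", i)
    cid <- sprintf("cell%03d", i)
    cen <- stats::runif(2L, 20, 80)
    start_frame <- if (spread_starts) sample.int(total_frames, 1L) else 1L
    lifetime <- if (disassembly_rate > 0) {
      stats::rgeom(1L, disassembly_rate) + 1L
    } else Inf
    natural_end <- start_frame + lifetime - 1L
    end_frame <- min(natural_end, total_frames)
    n_obs <- as.integer(end_frame - start_frame + 1L)
    theta <- stats::runif(1L, 0, 2 * pi)
    r0 <- stats::runif(1L, r0_range[1L], r0_range[2L])
    pos <- matrix(NA_real_, n_obs, 2L)
    pos[1L, ] <- cen + r0 * c(cos(theta), sin(theta))
    tail_start <- NA_integer_
    has_tail <- outward_frac > 0 && stats::runif(1L) < outward_frac &&
      n_obs > outward_len + 2L
    inward_until <- if (has_tail) n_obs - outward_len else n_obs
    if (has_tail) tail_start <- start_frame + inward_until
    if (n_obs > 1L) {
      for (f in 2:n_obs) {
        prev <- pos[f - 1L, ]
        v <- cen - prev
        dist <- sqrt(sum(v^2))
        step_drift <- if (f <= inward_until) {
          if (dist > drift) drift * v / dist else v
        } else {
          -outward_drift * v / max(dist, 1e-9)
        }
        pos[f, ] <- prev + step_drift + stats::rnorm(2L, 0, noise_sd)
      }
    }
    tracks[[tid]] <- data.frame(track_id = tid, cell_id = cid,
                                frame = seq.int(start_frame, end_frame),
                                x = pos[, 1L], y = pos[, 2L],
                                stringsAsFactors = FALSE)
    cells[[cid]] <- data.frame(cell_id = cid, centroid_x = cen[1L],
                               centroid_y = cen[2L],
                               stringsAsFactors = FALSE)
    truth[[tid]] <- data.frame(track_id = tid, cell_id = cid,
                               start_frame = start_frame,
                               end_frame = end_frame,
                               complete = is.finite(natural_end) &&
                                 natural_end < total_frames,
                               tail_start = tail_start, r0 = r0,
                               stringsAsFactors = FALSE)
  }
  list(tracks = do.call(rbind, c(unname(tracks),
                                 list(make.row.names = FALSE))),
       cells = do.call(rbind, c(unname(cells),
                                list(make.row.names = FALSE))),
       truth = do.call(rbind, c(unname(truth),
                                list(make.row.names = FALSE))),
       acquisition_end = total_frames)
}

#' Write / read sequence sets as FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path File path.
#' @return \code{write_fasta}: the path, invisibly; \code{read_fasta}: a
#'   named character vector.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}
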