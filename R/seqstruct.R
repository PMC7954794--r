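# Sequence and structure utilities: translation, alignment-based identity and
# conservation, relative solvent accessibility, atomic distances, ortholog
# domain-position conservation and circular-dichroism normalization.

#' Translate a DNA sequence with the standard genetic code
#'
#' @param dna A DNA string (A/C/G/T only), length divisible by 3. The empty
#'   string translates to the empty peptide.
#' @return One-letter peptide string; stop codons appear as \code{"*"}.
#' @examples
#' translate_dna("GGCGGAAGTTCTGGAGGTGGTGGT")  # "GGSSGGGG"
#' @export
translate_dna <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  dna <- toupper(dna)
  if (nchar(dna) == 0L) return("")
  if (nchar(dna) %% 3L != 0L) {
    stop("DNA length must be divisible by 3, got ", nchar(dna))
  }
  if (grepl("[^ACGT]", dna)) {
    stop("only A/C/G/T are accepted (no ambiguity codes)")
  }
  codons <- substring(dna, seq(1L, nchar(dna), 3L), seq(3L, nchar(dna), 3L))
  paste(codon_to_aa(codons), collapse = "")
}

# split an aligned row into residues; accepts a string or a character vector
as_residues <- function(x) {
  if (length(x) == 1L && nchar(x[1L]) > 1L) {
    strsplit(x, "")[[1L]]
  } else {
    as.character(x)
  }
}

#' Pairwise identity of two aligned sequences
#'
#' Fraction of matching residues over all columns in which at least one of
#' the two rows carries a residue. A gap aligned to a residue counts as a
#' mismatch; columns where both rows are gapped are excluded.
#'
#' @param a,b Aligned rows of equal length (strings or character vectors;
#'   gaps as \code{"-"}).
#' @return Fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  a <- as_residues(a)
  b <- as_residues(b)
  if (length(a) != length(b)) {
    stop("aligned rows differ in length (", length(a), " vs ", length(b), ")")
  }
  keep <- !(a == "-" & b == "-")
  if (!any(keep)) stop("no non-gap columns shared by the two rows")
  sum(a[keep] == b[keep] & a[keep] != "-") / sum(keep)
}

#' Per-column conservation of a multiple sequence alignment
#'
#' Scores each alignment column as the mean pairwise substitution-matrix
#' similarity over all unordered pairs of non-gap residues, after min-max
#' normalizing the matrix to \[0, 1\] over all its entries. A column of
#' identical tryptophans scores exactly 1 (W/W attains the BLOSUM62 maximum).
#'
#' @param aln Character matrix (rows = sequences, columns = positions) or a
#'   character vector of equal-length aligned strings.
#' @param sub_matrix 20x20 integer substitution matrix with residue
#'   dimnames; defaults to BLOSUM62.
#' @return Numeric vector of per-column scores; \code{NA} where fewer than
#'   two non-gap residues are present or an unknown residue occurs.
#' @export
site_conservation <- function(aln, sub_matrix = blosum62_matrix()) {
  if (!is.matrix(aln)) {
    rows <- lapply(aln, as_residues)
    if (length(unique(lengths(rows))) != 1L) stop("rows differ in length")
    aln <- do.call(rbind, rows)
  }
  if (nrow(aln) < 2L) stop("need at least two aligned rows")
  rng <- range(sub_matrix)
  norm <- (sub_matrix - rng[1L]) / (rng[2L] - rng[1L])
  apply(aln, 2L, function(col) {
    res <- col[col != "-"]
    if (length(res) < 2L) return(NA_real_)
    if (!all(res %in% rownames(norm))) {
      warning("unknown residue in column; scored NA")
      return(NA_real_)
    }
    pairs <- utils::combn(length(res), 2L)
    mean(norm[cbind(res[pairs[1L, ]], res[pairs[2L, ]])])
  })
}

#' Relative solvent accessibility
#'
#' Divides an absolute accessibility by the maximum accessibility of the
#' residue type. Values above 1 are possible with empirical maxima and are
#' flagged with a warning, never clamped.
#'
#' @param acc Accessibility in square Angstroms, >= 0.
#' @param aa One-letter residue code.
#' @param max_table Named numeric vector of per-residue maxima; defaults to
#'   the packaged empirical table.
#' @return RSA fraction (>= 0).
#' @export
rsa <- function(acc, aa, max_table = max_accessibility()) {
  stopifnot(is.numeric(acc), acc >= 0)
  if (!aa %in% names(max_table)) stop("no maximum accessibility for '", aa, "'")
  out <- acc / max_table[[aa]]
  if (out > 1) warning("RSA > 1 for residue ", aa, " (", signif(out, 3), ")")
  out
}

#' Minimum Euclidean distance between two atom sets
#'
#' @param atoms_a,atoms_b Numeric matrices with 3 columns (x, y, z
#'   coordinates in Angstroms), one row per atom.
#' @return Smallest cross-pair distance in Angstroms.
#' @export
min_distance <- function(atoms_a, atoms_b) {
  atoms_a <- as.matrix(atoms_a)
  atoms_b <- as.matrix(atoms_b)
  if (nrow(atoms_a) == 0L || nrow(atoms_b) == 0L) stop("empty atom set")
  stopifnot(ncol(atoms_a) == 3L, ncol(atoms_b) == 3L)
  d2 <- outer(rowSums(atoms_a^2), rowSums(atoms_b^2), "+") -
    2 * tcrossprod(atoms_a, atoms_b)
  sqrt(max(0, min(d2)))
}

#' Read atom coordinates from a PDB file
#'
#' Thin wrapper extracting the coordinate matrix of (optionally) one chain
#' from standard ATOM records; only coordinates are consumed.
#'
#' @param path PDB file path.
#' @param chain Optional chain identifier.
#' @param resno Optional residue-number filter.
#' @return Numeric matrix with columns x, y, z.
#' @export
read_pdb_coords <- function(path, chain = NULL, resno = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB files requires the 'bio3d' package")
  }
  pdb <- bio3d::read.pdb(path)
  atoms <- pdb$atom
  keep <- atoms$type == "ATOM"
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(resno)) keep <- keep & atoms$resno %in% resno
  as.matrix(atoms[keep, c("x", "y", "z")])
}

#' Build a domain record with its relative position
#'
#' @param protein,species Identifiers.
#' @param protein_length Full protein length in residues.
#' @param domain_start,domain_end 1-based domain envelope coordinates.
#' @return One-row data frame including \code{rel_position} =
#'   \code{domain_start / protein_length}.
#' @export
domain_record <- function(protein, species, protein_length,
                          domain_start, domain_end) {
  stopifnot(domain_start >= 1, domain_start <= domain_end,
            domain_end <= protein_length)
  data.frame(protein = protein, species = species,
             protein_length = protein_length,
             domain_start = domain_start, domain_end = domain_end,
             rel_position = domain_start / protein_length,
             stringsAsFactors = FALSE)
}

#' Positional conservation of orthologous domains
#'
#' An orthologous domain is positionally conserved when its relative start
#' position (domain start / protein length) lies within a fixed window of
#' the reference domain's relative position.
#'
#' @param ref One-row domain record for the reference protein (see
#'   [domain_record()]).
#' @param orthologs Data frame of ortholog domain records.
#' @param window Window half-width on the relative-position scale
#'   (default 0.10, i.e. 10\% of sequence length).
#' @return The ortholog table with a logical \code{conserved} column; the
#'   conserved fraction is attached as attribute \code{"fraction"}.
#' @export
domain_position_conservation <- function(ref, orthologs, window = 0.10) {
  stopifnot(nrow(ref) == 1L, "rel_position" %in% names(ref),
            "rel_position" %in% names(orthologs))
  out <- orthologs
  out$conserved <- abs(out$rel_position - ref$rel_position) <= window
  attr(out, "fraction") <- mean(out$conserved)
  out
}

#' Mean sequence similarity between a reference and its orthologs
#'
#' @param ref_row Aligned reference row.
#' @param ortholog_rows List (or character vector) of aligned ortholog rows.
#' @return Mean of the reference-vs-ortholog pairwise identities.
#' @export
mean_ortholog_similarity <- function(ref_row, ortholog_rows) {
  if (length(ortholog_rows) == 0L) stop("empty ortholog list")
  mean(vapply(ortholog_rows, function(r) pairwise_identity(ref_row, r),
              numeric(1L)))
}

#' Min-max normalized ellipticity
#'
#' Rescales a circular-dichroism ellipticity series (theta, mdeg) to
#' fractions: (theta - theta_min) / (theta_max - theta_min), with the
#' extrema taken over the series itself.
#'
#' @param theta Numeric vector of ellipticity values.
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
normalized_ellipticity <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) >= 2L)
  rng <- range(theta)
  if (rng[1L] == rng[2L]) stop("constant ellipticity series")
  (theta - rng[1L]) / (rng[2L] - rng[1L])
}

#' Stuffer-linker translation fixtures
#'
#' The two stuffer DNA sequences used to replace deleted SH3 domains, with
#' the flexible Gly/Ser linker peptides they encode. Useful as exact
#' translation test fixtures.
#'
#' @return Data frame with columns \code{dna} and \code{peptide} (2 rows).
#' @export
stuffer_fixtures <- function() {
  data.frame(
    dna = c("GGCGGAAGTTCTGGAGGTGGTGGT", "GGTGGCTCAGGAGGAGGTGGTGGA"),
    peptide = c("GGSSGGGG", "GGSGGGGG"),
    stringsAsFactors = FALSE
  )
}
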