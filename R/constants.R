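# Shared alphabets and lookup tables.

#' Standard amino-acid alphabet
#'
#' The 20 one-letter amino-acid codes, alphabetically ordered. This is the
#' canonical column order for PWM frequency matrices throughout the package.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Genetic code as a plain named vector (codon -> one-letter aa, "*" = stop).
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

# aa encoded by a codon; error on unknown codons
codon_to_aa <- function(codons) {
  gc <- genetic_code()
  bad <- setdiff(unique(codons), names(gc))
  if (length(bad) > 0L) {
    stop("unknown codon(s): ", paste(bad, collapse = ", "))
  }
  unname(gc[codons])
}

#' Maximum solvent accessibility per residue type
#'
#' Reads a table of empirical maximum solvent accessibilities (\eqn{\mathrm{\AA}^2})
#' used to convert absolute accessibilities into relative solvent
#' accessibility (RSA). The packaged default holds the widely used empirical
#' maxima of Tien et al. (2013); the table is configuration and can be
#' replaced by any two-column file (columns \code{aa}, \code{max_acc}).
#'
#' @param path Path to a tab-delimited table with columns \code{aa} and
#'   \code{max_acc}. Defaults to the packaged table.
#' @return Named numeric vector keyed by one-letter residue code.
#' @export
max_accessibility <- function(path = system.file("extdata",
                                                 "max_acc_empirical.tsv",
                                                 package = "sh3kit")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("aa", "max_acc") %in% names(tab)))
  stats::setNames(tab$max_acc, tab$aa)
}

# BLOSUM62 restricted to the 20 standard residues, in alphabet order.
blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  aa <- aa_alphabet()
  m[aa, aa]
}
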