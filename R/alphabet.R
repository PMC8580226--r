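# Amino-acid alphabet used throughout: the 20 standard residues plus 'X' for
# ambiguity. 'X' is accepted on input and scored with background frequencies;
# 'B', 'Z', 'U', 'J' are mapped to 'X' with a warning.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "X")

#' Encode an amino-acid string as integer codes
#'
#' Residues map to 1..20 in the order `ACDEFGHIKLMNPQRSTVWY`; `X` maps to 21.
#' @param seq single amino-acid string (uppercase, validated)
#' @return integer vector of codes
#' @keywords internal
.aa_encode <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], AA21)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop("non-amino-acid character at position ", bad, " in sequence")
  }
  codes
}

.aa_decode <- function(codes) {
  # 0 encodes a gap inside profile matrices
  out <- character(length(codes))
  out[codes == 0] <- "-"
  out[codes > 0] <- AA21[codes[codes > 0]]
  paste(out, collapse = "")
}

#' Substitution matrix over the 21-letter alphabet
#'
#' Fetches a named substitution matrix (default BLOSUM62) from
#' \pkg{Biostrings} and subsets it to the 20 standard residues plus X,
#' in the package's alphabet order. Cached after first use.
#' @param name matrix name, e.g. "BLOSUM62"
#' @return 21 x 21 numeric matrix
#' @keywords internal
.aa_submat <- function(name = "BLOSUM62") {
  key <- paste0("submat_", name)
  if (!is.null(.skc_cache[[key]])) return(.skc_cache[[key]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  full <- e[[name]]
  if (!all(AA21 %in% rownames(full)))
    stop("substitution matrix ", name, " lacks required residues")
  m <- full[AA21, AA21]
  storage.mode(m) <- "double"
  .skc_cache[[key]] <- m
  m
}

#' Background amino-acid frequencies of a protein set
#'
#' Global frequencies of the 20 standard residues across all sequences
#' ('X' ignored). Falls back to uniform 1/20 when fewer than 1000 residues
#' are available (tiny panels carry too little signal for a stable null).
#' @param proteins protein record data frame (see [read_fasta()])
#' @return named numeric vector of 20 frequencies summing to 1
#' @export
aa_background <- function(proteins) {
  all <- paste(proteins$sequence, collapse = "")
  counts <- table(factor(strsplit(all, "", fixed = TRUE)[[1]], levels = AA20))
  n <- sum(counts)
  if (n < 1000) return(setNames(rep(1 / 20, 20), AA20))
  setNames(as.numeric(counts) / n, AA20)
}
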