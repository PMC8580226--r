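# Readers/writers for the external formats the pipeline touches, with strict
# validation: protein FASTA, labeled TSV matrices, the module catalog and
# genome manifests.

NORM_STATES <- c("raw_counts", "sample_relative", "module_max", "row_max")

#' Construct a labeled matrix
#'
#' The pipeline's numeric carrier: a non-negative matrix with row and column
#' ids and a declared normalization state. The state may only change through
#' the declared normalization operations.
#'
#' @param values numeric matrix (or object coercible to one)
#' @param row_ids,col_ids character labels; default taken from dimnames
#' @param norm_state one of `r paste(NORM_STATES, collapse = ", ")`
#' @return a `labeled_matrix`
#' @export
labeled_matrix <- function(values, row_ids = rownames(values),
                           col_ids = colnames(values),
                           norm_state = "raw_counts") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  norm_state <- match.arg(norm_state, NORM_STATES)
  if (is.null(row_ids) || is.null(col_ids))
    stop("labeled_matrix requires row and column ids")
  if (length(row_ids) != nrow(values) || length(col_ids) != ncol(values))
    stop("label lengths do not match matrix dimensions")
  if (anyDuplicated(row_ids)) stop("duplicate row ids")
  if (anyDuplicated(col_ids)) stop("duplicate column ids")
  if (any(!is.finite(values))) stop("values must be finite")
  if (any(values < 0)) stop("values must be non-negative")
  dimnames(values) <- list(as.character(row_ids), as.character(col_ids))
  structure(values, norm_state = norm_state, class = c("labeled_matrix", "matrix", "array"))
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("labeled_matrix: %d x %d [%s]\n", nrow(x), ncol(x), norm_state(x)))
  print(head(unclass(x)[, seq_len(min(ncol(x), 8L)), drop = FALSE], 6L))
  invisible(x)
}

#' Normalization state of a labeled matrix
#' @param x a `labeled_matrix`
#' @return character scalar
#' @export
norm_state <- function(x) attr(x, "norm_state")

.set_norm_state <- function(x, state) {
  attr(x, "norm_state") <- match.arg(state, NORM_STATES)
  x
}

#' Read a protein FASTA file
#'
#' Sequences are uppercased, terminal `*` stop characters stripped, and the
#' residues validated against the 20-letter alphabet plus `X`. The ambiguity
#' codes `B`, `Z`, `U`, `J` are mapped to `X` with a warning. The protein id
#' is the first whitespace-delimited token of each header.
#'
#' @param path FASTA file
#' @param genome_id label recorded for every record; defaults to the file
#'   name without extension
#' @return data frame with columns `protein_id`, `genome_id`, `sequence`
#' @export
read_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(genome_id))
    genome_id <- tools::file_path_sans_ext(basename(path))
  # parsed by hand rather than via Biostrings: readAAStringSet silently drops
  # characters outside its alphabet, whereas this reader must reject them
  # with a position
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not FASTA-formatted: ", path)
  entry <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) stop("empty FASTA header in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein id(s): ", paste(dup, collapse = ", "))
  seqs <- vapply(split(lines[!hdr], entry[!hdr]),
                 paste, "", collapse = "")[as.character(seq_along(ids))]
  seqs[is.na(seqs)] <- ""
  seqs <- toupper(gsub("[ \t]", "", seqs))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs))) {
    bad <- ids[!nzchar(seqs)][1]
    stop("empty sequence for entry ", bad)
  }
  if (any(grepl("[BZUJ]", seqs))) {
    warning("ambiguous residues B/Z/U/J mapped to X in ", path)
    seqs <- chartr("BZUJ", "XXXX", seqs)
  }
  for (i in seq_along(seqs)) {
    hit <- regexpr(sprintf("[^%s]", paste(AA21, collapse = "")), seqs[i])
    if (hit > 0)
      stop("non-amino-acid character '", substr(seqs[i], hit, hit),
           "' at position ", hit, " in entry ", ids[i])
  }
  data.frame(protein_id = ids, genome_id = genome_id, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#' @param proteins protein record data frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(proteins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", proteins$protein_id, "\n", proteins$sequence), con)
  invisible(path)
}

#' Read several proteomes listed in a genome manifest
#'
#' The manifest is a TSV with columns `genome_id` and `fasta_path` (relative
#' paths resolved against the manifest's directory).
#' @param path manifest TSV
#' @return combined protein record data frame
#' @export
read_genome_manifest <- function(path) {
  man <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "fasta_path") %in% names(man)))
    stop("manifest must have columns genome_id, fasta_path")
  base <- dirname(path)
  out <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$fasta_path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_fasta(p, genome_id = man$genome_id[i])
  })
  res <- do.call(rbind, out)
  key <- paste(res$genome_id, res$protein_id)
  if (anyDuplicated(key))
    stop("duplicate (genome_id, protein_id): ", key[duplicated(key)][1])
  res
}

#' Read a labeled TSV matrix
#'
#' Tab-separated, first row column ids, first column row ids; `.` decimal.
#' Leading lines starting with `#` (provenance headers) are skipped. Missing
#' cells, ragged rows and negative values are rejected.
#'
#' @param path TSV file
#' @param orientation `"as_is"` keeps the file layout; `"transpose"` swaps
#'   rows and columns after reading
#' @return a [labeled_matrix()] with `norm_state = "raw_counts"`
#' @export
read_matrix_tsv <- function(path, orientation = c("as_is", "transpose")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines)
  offset <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 1) stop("no header row in ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(lines) < 2) stop("no rows in ", path)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop("ragged row at line ", offset[bad], " in ", path)
  }
  header <- cells[[1]]
  col_ids <- header[-1]
  row_ids <- vapply(cells[-1], `[`, "", 1L)
  vals <- suppressWarnings(
    t(vapply(cells[-1], function(x) as.numeric(x[-1]), numeric(length(col_ids)))))
  if (length(col_ids) == 1L) vals <- matrix(vals, ncol = 1L)
  if (anyNA(vals)) stop("missing or non-numeric cell in ", path)
  if (any(vals < 0)) stop("negative value in ", path)
  m <- labeled_matrix(vals, row_ids, col_ids, "raw_counts")
  if (orientation == "transpose")
    m <- labeled_matrix(t(unclass(m)), col_ids, row_ids, "raw_counts")
  m
}

#' Write a labeled matrix as TSV
#'
#' Values are printed with 15 significant digits so that a read/write
#' round-trip preserves them to at least 12 significant digits. Optional
#' provenance lines are written as leading `#` comments.
#'
#' @param matrix a [labeled_matrix()]
#' @param path output file
#' @param header_comments character vector of comment lines (without `#`)
#' @return `path`, invisibly
#' @export
write_matrix_tsv <- function(matrix, path, header_comments = NULL) {
  stopifnot(inherits(matrix, "labeled_matrix"))
  labs <- c(rownames(matrix), colnames(matrix))
  if (any(grepl("[\t\n]", labs))) stop("labels must not contain tab or newline")
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  if (length(header_comments))
    writeLines(paste0("# ", header_comments), con)
  writeLines(paste(c("id", colnames(matrix)), collapse = "\t"), con)
  body <- apply(unclass(matrix), 1, function(r)
    paste(sprintf("%.15g", r), collapse = "\t"))
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

#' Read a module catalog
#'
#' A TSV with columns `pathway`, `module_id`, `model_name` mapping curated
#' co-metabolism pathways to their member gene models. A model may belong to
#' exactly one module; violations are an error (summing would otherwise
#' double-count).
#'
#' @param path catalog TSV; default is the catalog shipped with the package
#'   transcribing the curated pathway table
#' @return data frame of class `module_catalog`
#' @export
read_module_catalog <- function(path = system.file("extdata", "modules_table1.tsv",
                                                   package = "skincomet")) {
  cat <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("pathway", "module_id", "model_name")
  if (!all(need %in% names(cat)))
    stop("catalog must have columns ", paste(need, collapse = ", "))
  if (any(!nzchar(cat$pathway)) || any(!nzchar(cat$model_name)))
    stop("catalog has empty pathway or model_name")
  dup <- unique(cat$model_name[duplicated(cat$model_name)])
  if (length(dup))
    stop("model(s) listed under more than one module: ",
         paste(dup, collapse = ", "))
  class(cat) <- c("module_catalog", "data.frame")
  cat
}

#' Member models of each module (or pathway)
#' @param catalog a `module_catalog`
#' @param by group by `"module_id"` or `"pathway"`
#' @return named list of character vectors of model names
#' @export
module_members <- function(catalog, by = c("module_id", "pathway")) {
  by <- match.arg(by)
  split(catalog$model_name, catalog[[by]])
}

#' Read a seed-gene table
#'
#' TSV with columns `gene_symbol`, `locus_tag`, `organism`, `pathway`; every
#' row must carry a gene symbol and a pathway present in the module catalog.
#' @param path TSV file
#' @param catalog optional `module_catalog` used to validate pathway names
#' @return data frame
#' @export
read_seed_genes <- function(path, catalog = NULL) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = NULL)
  need <- c("gene_symbol", "locus_tag", "organism", "pathway")
  if (!all(need %in% names(tab)))
    stop("seed gene table must have columns ", paste(need, collapse = ", "))
  if (any(!nzchar(tab$gene_symbol)) || any(!nzchar(tab$pathway)))
    stop("seed gene rows must have non-empty gene_symbol and pathway")
  if (!is.null(catalog)) {
    unknown <- setdiff(tab$pathway, catalog$pathway)
    if (length(unknown))
      stop("seed gene pathway(s) not in catalog: ", paste(unknown, collapse = ", "))
  }
  tab
}
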