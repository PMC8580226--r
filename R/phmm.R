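# Profile hidden Markov models over the curated gene families: architecture
# selection from the alignment, Laplace-smoothed emission and transition
# estimates, forward/Viterbi log-odds scoring in a unihit local mode with
# uniform entry/exit, and gathering-threshold (GA) calibration.
#
# Scoring semantics (shared by calibration and scanning, so GA thresholds are
# internally consistent): log2 odds of the sequence under the profile versus
# the background null. Residues outside the matched segment are emitted by
# flanking states at background frequencies, contributing zero bits. Entry is
# uniform over match states (prob 1/M); exit from M_k has probability
# 1/(M - k + 1) (so fragment end points are uniform), core transitions out of
# M_k being scaled by one minus that; D_M exits with probability 1. Insert
# emissions equal the background, hence score zero.

#' Select match columns of an alignment
#'
#' A column becomes a match state iff its gap fraction is strictly below
#' `max_gap_frac`; all other columns are insert columns.
#'
#' @param msa an [msa]
#' @param max_gap_frac gap-fraction cutoff (default 0.5, strict inequality)
#' @return logical vector, one flag per column (`TRUE` = match)
#' @export
select_match_columns <- function(msa, max_gap_frac = 0.5) {
  chars <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  gf <- colMeans(chars == "-")
  flags <- gf < max_gap_frac
  if (!any(flags)) stop("no match columns")
  flags
}

# Per-row core state path through the flagged architecture. Returns a matrix
# with columns state ("M","I","D") and node; flank inserts (before node 1 or
# after node M) are emitted by the flanking states and skipped.
.state_path <- function(row_chars, match_flags) {
  M <- sum(match_flags)
  k <- 0L
  st <- character(0); nd <- integer(0)
  for (i in seq_along(row_chars)) {
    if (match_flags[i]) {
      k <- k + 1L
      st <- c(st, if (row_chars[i] == "-") "D" else "M"); nd <- c(nd, k)
    } else if (row_chars[i] != "-" && k >= 1L && k < M) {
      st <- c(st, "I"); nd <- c(nd, k)
    }
  }
  list(state = st, node = nd)
}

#' Build a profile HMM from an alignment
#'
#' Match emissions are Laplace-smoothed column residue frequencies
#' (`(count + pseudocount) / (non-gap count + 20 * pseudocount)`; `X`
#' residues are treated as missing). Insert emissions equal the background.
#' Transitions are estimated from per-row state paths with pseudocount 1 on
#' each transition type.
#'
#' @param msa an [msa]
#' @param match_flags from [select_match_columns()]; computed if `NULL`
#' @param pseudocount emission pseudocount (default 1)
#' @param background 20 background frequencies; uniform if `NULL`
#' @param name model name
#' @return a `profile_hmm` object
#' @export
build_profile <- function(msa, match_flags = NULL, pseudocount = 1,
                          background = NULL, name = "model") {
  if (is.null(match_flags)) match_flags <- select_match_columns(msa)
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), AA20)
  background <- background / sum(background)
  chars <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  M <- sum(match_flags)
  mcols <- which(match_flags)
  me <- matrix(0, M, 20, dimnames = list(NULL, AA20))
  for (k in seq_len(M)) {
    col <- chars[, mcols[k]]
    col <- col[col != "-" & col != "X"]
    cnt <- table(factor(col, levels = AA20))
    me[k, ] <- (as.numeric(cnt) + pseudocount) /
      (length(col) + 20 * pseudocount)
  }
  ie <- matrix(rep(background, each = M + 1), M + 1, 20,
               dimnames = list(NULL, AA20))
  # transition counts out of each node
  c3 <- matrix(0, M, 3, dimnames = list(NULL, c("MM", "MI", "MD")))
  cI <- matrix(0, M, 2, dimnames = list(NULL, c("IM", "II")))
  cD <- matrix(0, M, 2, dimnames = list(NULL, c("DM", "DD")))
  for (r in seq_len(nrow(chars))) {
    p <- .state_path(chars[r, ], match_flags)
    if (length(p$state) < 2) next
    for (i in seq_len(length(p$state) - 1)) {
      a <- p$state[i]; b <- p$state[i + 1]; k <- p$node[i]
      if (a == "M") {
        if (b == "M") c3[k, "MM"] <- c3[k, "MM"] + 1
        else if (b == "I") c3[k, "MI"] <- c3[k, "MI"] + 1
        else c3[k, "MD"] <- c3[k, "MD"] + 1
      } else if (a == "I") {
        if (b == "M") cI[k, "IM"] <- cI[k, "IM"] + 1
        else cI[k, "II"] <- cI[k, "II"] + 1
      } else {
        if (b == "M") cD[k, "DM"] <- cD[k, "DM"] + 1
        else cD[k, "DD"] <- cD[k, "DD"] + 1
      }
    }
  }
  trans <- matrix(NA_real_, M, 7,
                  dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  if (M > 1) {
    v <- seq_len(M - 1)
    tot3 <- rowSums(c3[v, , drop = FALSE]) + 3
    trans[v, c("MM", "MI", "MD")] <- (c3[v, , drop = FALSE] + 1) / tot3
    totI <- rowSums(cI[v, , drop = FALSE]) + 2
    trans[v, c("IM", "II")] <- (cI[v, , drop = FALSE] + 1) / totI
    totD <- rowSums(cD[v, , drop = FALSE]) + 2
    trans[v, c("DM", "DD")] <- (cD[v, , drop = FALSE] + 1) / totD
  }
  structure(list(name = name, M = M, match_emissions = me,
                 insert_emissions = ie, transitions = trans,
                 background = setNames(as.numeric(background), AA20),
                 ga_bits = NULL, ga_overlap = FALSE,
                 members = msa$row_ids),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s': M = %d, GA = %s, %d training members\n",
              x$name, x$M,
              if (is.null(x$ga_bits)) "unset" else sprintf("%.2f", x$ga_bits),
              length(x$members)))
  invisible(x)
}

# Probability/odds-space model parameters for the scaled forward kernel, in
# the destination-node layout (see .phmm_dp_args below). Computed once per
# model and reused across sequences.
.phmm_model_params <- function(hmm) {
  M <- hmm$M
  odds <- rbind(t(hmm$match_emissions) / hmm$background, X = 1)
  ex <- 1 / (M - seq_len(M) + 1)
  z <- rep(0, M)
  p <- list(odds = odds, pMM = z, pMI = z, pMD = z, pIM = z, pII = z,
            pDM = z, pDD = z, pEntry = 1 / M, pExit = ex)
  if (M > 1) {
    k <- seq_len(M - 1)
    keep <- 1 - ex[k]
    tr <- hmm$transitions
    p$pMM[k + 1] <- keep * tr[k, "MM"]
    p$pMD[k + 1] <- keep * tr[k, "MD"]
    p$pDM[k + 1] <- tr[k, "DM"]
    p$pDD[k + 1] <- tr[k, "DD"]
    p$pIM[k + 1] <- tr[k, "IM"]
    p$pMI[k + 1] <- keep * tr[k, "MI"]  # position k+1 = out of node k
    p$pII[k + 1] <- tr[k, "II"]
  }
  p
}

.forward_nats <- function(params, codes) {
  .phmm_forward_scaled_cpp(codes, params$odds, params$pMM, params$pMI,
                           params$pMD, params$pIM, params$pII, params$pDM,
                           params$pDD, params$pEntry, params$pExit)
}

# Assemble the log-space DP arguments in the layout the C++ kernels expect:
# vectors indexed by the *destination* node k hold the transition from node
# k-1 (MM, MD, DM, IM, DD), while MI/II at position k+1 hold the transition
# out of node k into its insert state.
.phmm_dp_args <- function(hmm, seq) {
  M <- hmm$M
  codes <- .aa_encode(seq)
  L <- length(codes)
  lo <- log(hmm$match_emissions / rep(hmm$background, each = M))
  em <- matrix(0, L, M)
  std <- codes <= 20
  em[std, ] <- t(lo[, codes[std], drop = FALSE])  # X rows stay 0
  ex <- 1 / (M - seq_len(M) + 1)
  ninf <- rep(-Inf, M)
  a <- list(em = em, lMM = ninf, lMI = ninf, lMD = ninf, lIM = ninf,
            lII = ninf, lDM = ninf, lDD = ninf,
            lEntry = log(1 / M), lExit = log(ex))
  if (M > 1) {
    k <- seq_len(M - 1)                      # source node
    keep <- log(1 - ex[k])
    tr <- hmm$transitions
    a$lMM[k + 1] <- keep + log(tr[k, "MM"])
    a$lMD[k + 1] <- keep + log(tr[k, "MD"])
    a$lDM[k + 1] <- log(tr[k, "DM"])
    a$lDD[k + 1] <- log(tr[k, "DD"])
    a$lIM[k + 1] <- log(tr[k, "IM"])
    a$lMI[k + 1] <- keep + log(tr[k, "MI"])  # position k+1 = out of node k
    a$lII[k + 1] <- log(tr[k, "II"])
  }
  a
}

#' Forward log-odds score of a sequence against a profile
#'
#' Sum over all state paths through the local architecture, in log space.
#' `X` residues emit the background and contribute zero bits.
#'
#' @param hmm a `profile_hmm`
#' @param seq amino-acid string
#' @return score in bits (log2 odds); always finite
#' @export
score_forward <- function(hmm, seq) {
  if (!nzchar(seq)) stop("empty sequence")
  .forward_nats(.phmm_model_params(hmm), .aa_encode(seq)) / log(2)
}

#' Viterbi score and state path
#'
#' Maximum-probability path companion to [score_forward()]; its score never
#' exceeds the forward score.
#'
#' @inheritParams score_forward
#' @return list with `bits` and `path` (labels like `"M1"`, `"I2"`, `"D3"`)
#' @export
score_viterbi <- function(hmm, seq) {
  if (!nzchar(seq)) stop("empty sequence")
  a <- .phmm_dp_args(hmm, seq)
  res <- .phmm_viterbi_cpp(a$em, a$lMM, a$lMI, a$lMD, a$lIM, a$lII,
                           a$lDM, a$lDD, a$lEntry, a$lExit)
  k <- res$path %/% 3L
  s <- c("M", "I", "D")[res$path %% 3L + 1L]
  list(bits = res$logodds / log(2), path = paste0(s, k))
}

#' Score a set of proteins against a set of models
#'
#' @param models list of `profile_hmm`
#' @param proteins protein record data frame
#' @return numeric matrix of bits, proteins (rows, named by protein id) x
#'   models (columns, named by model name)
#' @export
score_matrix <- function(models, proteins) {
  codes <- lapply(proteins$sequence, .aa_encode)
  out <- vapply(models, function(h) {
    p <- .phmm_model_params(h)
    vapply(codes, function(cc) .forward_nats(p, cc), 0.0) / log(2)
  }, numeric(nrow(proteins)))
  if (nrow(proteins) == 1L) out <- matrix(out, nrow = 1L)
  dimnames(out) <- list(proteins$protein_id,
                        vapply(models, `[[`, "", "name"))
  out
}

#' Calibrate the gathering threshold (GA) of a model
#'
#' The model's orthogroup members are the true positives and all other panel
#' proteins the true negatives; the GA is the average of the lowest-scoring
#' true positive and the highest-scoring true negative. When the score ranges
#' overlap (highest negative >= lowest positive) an overlap flag is raised.
#' With no negatives available, GA falls back to `min(positives) - 0.5` bits,
#' flagged.
#'
#' @param hmm a `profile_hmm`
#' @param positives protein records of the model's orthogroup members
#' @param negatives protein records of all other panel proteins
#' @param scores optional precomputed bit scores (named by protein id, e.g. a
#'   [score_matrix()] column) to avoid rescoring
#' @return the model with `ga_bits` and `ga_overlap` set
#' @export
calibrate_ga <- function(hmm, positives, negatives, scores = NULL) {
  if (is.null(positives) || nrow(positives) == 0) stop("empty positives")
  get_scores <- function(recs) {
    if (!is.null(scores)) return(unname(scores[recs$protein_id]))
    vapply(recs$sequence, function(s) score_forward(hmm, s), 0.0,
           USE.NAMES = FALSE)
  }
  pos <- get_scores(positives)
  if (is.null(negatives) || nrow(negatives) == 0) {
    hmm$ga_bits <- min(pos) - 0.5
    hmm$ga_overlap <- TRUE
    warning("no negatives for model ", hmm$name,
            "; GA set to min(positives) - 0.5 bits")
    return(hmm)
  }
  neg <- get_scores(negatives)
  hmm$ga_bits <- (min(pos) + max(neg)) / 2
  hmm$ga_overlap <- max(neg) >= min(pos)
  hmm
}

#' Score report for proteins against one model
#'
#' @param hmm a calibrated `profile_hmm`
#' @param proteins protein record data frame
#' @return data frame: `model_name`, `protein_id`, `bits`, `passes_ga`
#' @export
score_report <- function(hmm, proteins) {
  if (is.null(hmm$ga_bits)) stop("model ", hmm$name, " has no GA threshold")
  bits <- vapply(proteins$sequence, function(s) score_forward(hmm, s), 0.0,
                 USE.NAMES = FALSE)
  data.frame(model_name = hmm$name, protein_id = proteins$protein_id,
             bits = bits, passes_ga = bits >= hmm$ga_bits,
             stringsAsFactors = FALSE)
}

.fmt_nlp <- function(p) {
  # negative natural-log probability; '*' encodes probability zero / unset
  ifelse(is.na(p) | p <= 0, "*", sprintf("%.17g", -log(p)))
}

.parse_nlp <- function(x) {
  out <- rep(0, length(x))
  num <- x != "*"
  out[num] <- exp(-as.numeric(x[num]))
  out
}

#' Write a model collection to a text file
#'
#' One block per model in a HMMER3-style text dialect: header lines (`NAME`,
#' `LENG`, `GA`, `MEMB`, `BG`), per-node `MATCH`/`INSERT`/`TRANS` lines with
#' negative natural-log probabilities (`*` for zero/undefined), terminated by
#' `//`. Round-trips preserve probabilities to well beyond 9 significant
#' digits and the GA exactly.
#'
#' @param models list of `profile_hmm`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_model_file <- function(models, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  writeLines("SKINCOMET-HMM 1.0", con)
  for (h in models) {
    writeLines(c(
      paste("NAME", h$name),
      paste("LENG", h$M),
      paste("GA", if (is.null(h$ga_bits)) "-" else sprintf("%.17g", h$ga_bits)),
      paste("OVERLAP", as.integer(isTRUE(h$ga_overlap))),
      paste("MEMB", if (length(h$members)) paste(h$members, collapse = ",") else "-"),
      paste("BG", paste(.fmt_nlp(h$background), collapse = " "))), con)
    for (k in seq_len(h$M))
      writeLines(paste("MATCH", k,
                       paste(.fmt_nlp(h$match_emissions[k, ]), collapse = " ")), con)
    for (k in seq_len(h$M + 1))
      writeLines(paste("INSERT", k,
                       paste(.fmt_nlp(h$insert_emissions[k, ]), collapse = " ")), con)
    for (k in seq_len(h$M))
      writeLines(paste("TRANS", k,
                       paste(.fmt_nlp(h$transitions[k, ]), collapse = " ")), con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Read a model collection written by [write_model_file()]
#'
#' Malformed or truncated files raise an error naming the offending line.
#' Models whose `GA` field is `-` load with an unset threshold; scanning
#' them is an error until calibrated.
#'
#' @param path model collection file
#' @return list of `profile_hmm`, named by model name
#' @export
read_model_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "SKINCOMET-HMM 1.0")
    stop("line 1: not a skincomet model file")
  i <- 2L
  fail <- function(msg, at = i) stop("line ", at, ": ", msg)
  expect <- function(key) {
    if (i > length(lines)) fail(paste0("truncated file (expected ", key, ")"),
                                at = length(lines))
    parts <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (parts[1] != key) fail(paste0("expected ", key, " line"))
    i <<- i + 1L
    parts[-1]
  }
  models <- list()
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    name <- paste(expect("NAME"), collapse = " ")
    M <- as.integer(expect("LENG"))
    if (is.na(M) || M < 1) fail("bad LENG", at = i - 1L)
    ga_raw <- expect("GA")
    ga <- if (identical(ga_raw, "-")) NULL else as.numeric(ga_raw)
    ov <- as.integer(expect("OVERLAP")) == 1L
    memb_raw <- expect("MEMB")
    memb <- if (identical(memb_raw, "-")) character(0)
            else strsplit(memb_raw, ",", fixed = TRUE)[[1]]
    bg <- .parse_nlp(expect("BG"))
    if (length(bg) != 20) fail("BG needs 20 values", at = i - 1L)
    grab <- function(key, n_expect, rows) {
      m <- matrix(NA_real_, rows, n_expect)
      for (k in seq_len(rows)) {
        v <- expect(key)
        if (as.integer(v[1]) != k) fail(paste0(key, " rows out of order"), i - 1L)
        if (length(v) - 1 != n_expect) fail(paste0("bad ", key, " row"), i - 1L)
        m[k, ] <- .parse_nlp(v[-1])
      }
      m
    }
    me <- grab("MATCH", 20, M); colnames(me) <- AA20
    ie <- grab("INSERT", 20, M + 1); colnames(ie) <- AA20
    tr <- grab("TRANS", 7, M)
    colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
    tr[tr == 0] <- NA_real_  # '*' in TRANS rows means undefined
    if (i > length(lines) || lines[i] != "//") fail("expected // terminator")
    i <- i + 1L
    h <- structure(list(name = name, M = M, match_emissions = me,
                        insert_emissions = ie, transitions = tr,
                        background = setNames(bg, AA20), ga_bits = ga,
                        ga_overlap = ov, members = memb),
                   class = "profile_hmm")
    models[[name]] <- h
  }
  if (!length(models)) stop("no models in ", path)
  models
}
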