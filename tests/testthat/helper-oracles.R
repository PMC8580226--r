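# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (path enumeration, per-column least squares,
# exhaustive alignment) rather than calling the implementation under test.

# --- exhaustive path enumeration for the local profile HMM ------------------
# Mirrors the scoring semantics from first principles: uniform entry 1/M into
# any match state at any sequence position (flanks emit at zero log-odds),
# exit from M_k with probability 1/(M-k+1) and core transitions out of M_k
# scaled by the complement, D_M exiting with probability 1, insert emissions
# at the background. Returns forward (sum) and Viterbi (max) bits.
enumerate_paths <- function(hmm, seq) {
  M <- hmm$M
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], c(skincomet:::AA20, "X"))
  L <- length(codes)
  odds <- function(k, j) {
    if (codes[j] == 21) return(1)
    hmm$match_emissions[k, codes[j]] / hmm$background[codes[j]]
  }
  ex <- 1 / (M - seq_len(M) + 1)
  tr <- hmm$transitions
  weights <- numeric(0)
  recurse <- function(state, k, j, w) {
    # 'w' is the odds weight having just processed (state, k) with j residues
    # consumed; collect every legal completion.
    if (state == "M") {
      weights[[length(weights) + 1L]] <<- w * ex[k]     # exit M_k -> E
      if (k < M) {
        keep <- 1 - ex[k]
        if (j < L) {
          recurse("M", k + 1, j + 1, w * keep * tr[k, "MM"] * odds(k + 1, j + 1))
          recurse("I", k, j + 1, w * keep * tr[k, "MI"])
        }
        recurse("D", k + 1, j, w * keep * tr[k, "MD"])
      }
    } else if (state == "I") {
      if (j < L) {
        recurse("M", k + 1, j + 1, w * tr[k, "IM"] * odds(k + 1, j + 1))
        recurse("I", k, j + 1, w * tr[k, "II"])
      }
    } else { # D
      if (k == M) {
        weights[[length(weights) + 1L]] <<- w            # D_M -> E, prob 1
      } else {
        if (j < L)
          recurse("M", k + 1, j + 1, w * tr[k, "DM"] * odds(k + 1, j + 1))
        recurse("D", k + 1, j, w * tr[k, "DD"])
      }
    }
  }
  for (p in seq_len(L))        # first matched residue position
    for (k in seq_len(M))      # entry node
      recurse("M", k, p, (1 / M) * odds(k, p))
  list(forward_bits = log2(sum(weights)), viterbi_bits = log2(max(weights)))
}

# Random small valid profile HMM for oracle comparisons.
random_toy_hmm <- function(M, seed) {
  set.seed(seed)
  rdir <- function(n) { x <- rgamma(n, 1); x / sum(x) }
  me <- t(vapply(seq_len(M), function(k) rdir(20), numeric(20)))
  colnames(me) <- skincomet:::AA20
  bg <- rdir(20)
  tr <- matrix(NA_real_, M, 7,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  if (M > 1) for (k in seq_len(M - 1)) {
    tr[k, c("MM", "MI", "MD")] <- rdir(3)
    tr[k, c("IM", "II")] <- rdir(2)
    tr[k, c("DM", "DD")] <- rdir(2)
  }
  structure(list(name = sprintf("toy%d", seed), M = M, match_emissions = me,
                 insert_emissions = matrix(rep(bg, each = M + 1), M + 1, 20),
                 transitions = tr, background = setNames(bg, skincomet:::AA20),
                 ga_bits = NULL, ga_overlap = FALSE, members = character(0)),
            class = "profile_hmm")
}

random_aa_seq <- function(len) paste(sample(skincomet:::AA20, len, TRUE), collapse = "")

# --- brute-force RDA variance-explained oracle ------------------------------
# Sum over response columns of the univariate regression SS on the centered
# constraint, over the total centered SS.
rda_oracle_var <- function(Y, x) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  xc <- x - mean(x)
  ssf <- sum(vapply(seq_len(ncol(Yc)), function(j) {
    b <- sum(Yc[, j] * xc) / sum(xc^2)
    sum((b * xc)^2)
  }, 0.0))
  ssf / sum(Yc^2)
}

# --- tiny protein record helpers --------------------------------------------
prot_df <- function(ids, genomes, seqs)
  data.frame(protein_id = ids, genome_id = genomes, sequence = seqs,
             stringsAsFactors = FALSE)

write_tmp_fasta <- function(entries, path = tempfile(fileext = ".faa")) {
  writeLines(unlist(lapply(names(entries), function(n)
    c(paste0(">", n), entries[[n]]))), path)
  path
}
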