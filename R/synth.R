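# Synthetic fixtures with known ground truth for every stage: evolved
# protein families planted in reference proteomes, OTU tables with group
# structure, and phenotype tables tied to a latent age variable. Defaults
# state the emulated world: a panel of 10 skin-bacteria-scale genomes with
# 12 gene families at 15% within-family divergence, a 2 x 25 two-age-group
# swab design, and eight clinical measurements loading on latent age.

.random_protein <- function(length, bg = NULL) {
  if (is.null(bg)) bg <- rep(1 / 20, 20)
  paste(sample(AA20, length, replace = TRUE, prob = bg), collapse = "")
}

#' Evolve a protein family from a seed sequence
#'
#' Each copy derives from the seed by i.i.d. substitutions (uniform over the
#' 19 alternative residues) at rate `sub_rate` per site, and indels at rate
#' `indel_rate` per site (insertion or deletion with equal probability,
#' geometric length with mean 2). Deterministic given `seed`.
#'
#' @param seed_seq ancestral amino-acid string
#' @param n_copies number of descendant copies
#' @param sub_rate,indel_rate per-site rates in `[0, 0.5]`
#' @param seed RNG seed
#' @return character vector of `n_copies` sequences
#' @export
evolve_family <- function(seed_seq, n_copies, sub_rate = 0.15,
                          indel_rate = 0, seed = 1) {
  if (sub_rate < 0 || sub_rate > 0.5 || indel_rate < 0 || indel_rate > 0.5)
    stop("rates must lie in [0, 0.5]")
  set.seed(seed)
  base <- strsplit(seed_seq, "", fixed = TRUE)[[1]]
  vapply(seq_len(n_copies), function(i) {
    s <- base
    hit <- runif(length(s)) < sub_rate
    if (any(hit))
      s[hit] <- vapply(s[hit], function(a)
        sample(setdiff(AA20, a), 1), "", USE.NAMES = FALSE)
    if (indel_rate > 0) {
      out <- character(0)
      for (j in seq_along(s)) {
        if (runif(1) < indel_rate) {
          len <- rgeom(1, 0.5) + 1
          if (runif(1) < 0.5) {           # insertion before site j
            out <- c(out, sample(AA20, len, replace = TRUE), s[j])
          } else {                         # deletion starting at site j
            next
          }
        } else out <- c(out, s[j])
      }
      if (!length(out)) out <- sample(AA20, 1)
      s <- out
    }
    paste(s, collapse = "")
  }, "")
}

#' Simulate a reference proteome panel with planted gene families
#'
#' Each genome receives, per family, a number of copies drawn from
#' `copy_probs` (default: absent 15%, single copy 70%, duplicated 15%),
#' evolved from the family seed sequence at `sub_rate`, plus unrelated decoy
#' proteins drawn from the background composition. Families are redrawn until
#' they have at least two members panel-wide (a family needs an alignable
#' orthogroup). The planted copy-number matrix and member registry are
#' returned as ground truth.
#'
#' @param n_genomes,n_families panel dimensions (defaults 10 and 12)
#' @param copy_probs probabilities of 0, 1, 2 copies per genome
#' @param n_decoys decoy proteins per genome (default 8)
#' @param seq_length seed sequence length (default 250 aa, typical bacterial
#'   enzyme scale)
#' @param sub_rate within-family divergence (default 0.15)
#' @param indel_rate per-site indel rate within families (default 0)
#' @param dup_sub_rate divergence of a second (duplicated) copy from its
#'   co-resident first copy (default 0.03): duplicates are recent
#'   in-paralogs, more similar to each other than to any cross-genome homolog
#' @param seed RNG seed
#' @return list with `proteins` (protein records), `model_names`, and
#'   `truth` (`copy_number` genome x family matrix, `members` registry,
#'   `config`)
#' @export
simulate_panel <- function(n_genomes = 10, n_families = 12,
                           copy_probs = c(0.15, 0.7, 0.15), n_decoys = 8,
                           seq_length = 250, sub_rate = 0.15,
                           indel_rate = 0, dup_sub_rate = 0.03, seed = 17) {
  stopifnot(n_genomes >= 2, n_families >= 1, length(copy_probs) == 3)
  set.seed(seed)
  genomes <- sprintf("g%02d", seq_len(n_genomes))
  fams <- sprintf("fam%02d", seq_len(n_families))
  seeds <- vapply(fams, function(f) .random_protein(seq_length), "")
  cn <- matrix(0L, n_genomes, n_families, dimnames = list(genomes, fams))
  for (f in seq_len(n_families)) {
    repeat {
      draw <- sample(0:2, n_genomes, replace = TRUE, prob = copy_probs)
      if (sum(draw) >= 2) break
    }
    cn[, f] <- draw
  }
  fam_seeds <- sample.int(.Machine$integer.max %/% 2, n_families)
  dup_seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                                 n_families * n_genomes),
                      n_genomes, n_families)
  decoy_seed <- sample.int(.Machine$integer.max %/% 2, 1)
  prot <- list()
  members <- list()
  for (f in seq_len(n_families)) {
    present <- which(cn[, f] >= 1L)
    primaries <- evolve_family(seeds[f], length(present), sub_rate,
                               indel_rate, seed = fam_seeds[f])
    for (i in seq_along(present)) {
      g <- present[i]
      for (c in seq_len(cn[g, f])) {
        sq <- if (c == 1L) primaries[i]
              else evolve_family(primaries[i], 1, dup_sub_rate, 0,
                                 seed = dup_seeds[g, f])
        pid <- sprintf("%s_%s_%d", genomes[g], fams[f], c)
        prot[[length(prot) + 1L]] <- data.frame(
          protein_id = pid, genome_id = genomes[g],
          sequence = sq, stringsAsFactors = FALSE)
        members[[length(members) + 1L]] <- data.frame(
          model = fams[f], genome_id = genomes[g], protein_id = pid,
          stringsAsFactors = FALSE)
      }
    }
  }
  set.seed(decoy_seed)
  for (g in seq_len(n_genomes)) for (d in seq_len(n_decoys)) {
    pid <- sprintf("%s_decoy_%d", genomes[g], d)
    prot[[length(prot) + 1L]] <- data.frame(
      protein_id = pid, genome_id = genomes[g],
      sequence = .random_protein(seq_length), stringsAsFactors = FALSE)
  }
  proteins <- do.call(rbind, prot)
  list(proteins = proteins, model_names = fams,
       truth = list(copy_number = cn,
                    members = do.call(rbind, members),
                    config = list(n_genomes = n_genomes,
                                  n_families = n_families,
                                  copy_probs = copy_probs,
                                  n_decoys = n_decoys,
                                  seq_length = seq_length,
                                  sub_rate = sub_rate,
                                  indel_rate = indel_rate,
                                  dup_sub_rate = dup_sub_rate, seed = seed)))
}

#' Simulate a 16S community with two-group structure
#'
#' One OTU per panel genome. Per-OTU base relative abundances are log-normal;
#' samples in the second group have designated OTUs multiplied by
#' `effect_size`; counts are multinomial at the stated depth. Emulates the
#' two-age-group cheek-swab design (2 x 25 by default). Taxonomies are
#' seven-rank strings shared with the panel, so OTUs map one-to-one onto
#' genomes.
#'
#' @param genomes character vector of genome ids (OTU per genome)
#' @param n_samples total samples, split evenly into groups (default 50)
#' @param effect_size multiplicative group effect on affected OTUs (1 = none)
#' @param n_affected number of affected OTUs
#' @param sigma_log log-scale dispersion of base abundances
#' @param depth reads per sample (> 0)
#' @param seed RNG seed
#' @return list with `otus` (an [otu_data()]), `panel_taxa`, and `truth`
#'   (`group` factor, `affected` OTU ids, `base_abundance`)
#' @export
simulate_community <- function(genomes, n_samples = 50, effect_size = 3,
                               n_affected = 3, sigma_log = 1,
                               depth = 10000, seed = 1) {
  if (depth <= 0) stop("depth must be positive")
  if (n_samples < 2) stop("need at least 2 samples")
  set.seed(seed)
  nG <- length(genomes)
  otu_ids <- paste0("OTU_", genomes)
  panel_taxa <- setNames(sprintf(
    "Bacteria;Phylum%02d;Class%02d;Order%02d;Family%02d;Genus_%s;Species_%s",
    seq_len(nG) %% 4 + 1, seq_len(nG) %% 4 + 1, seq_len(nG), seq_len(nG),
    genomes, genomes), genomes)
  taxonomy <- setNames(unname(panel_taxa), otu_ids)
  base <- rlnorm(nG, 0, sigma_log)
  group <- factor(rep(c("young", "old"), length.out = n_samples),
                  levels = c("young", "old"))
  affected <- sample(otu_ids, min(n_affected, nG))
  counts <- matrix(0, n_samples, nG,
                   dimnames = list(sprintf("S%03d", seq_len(n_samples)), otu_ids))
  for (i in seq_len(n_samples)) {
    lam <- base * rlnorm(nG, 0, sigma_log / 2)
    if (group[i] == "old")
      lam[otu_ids %in% affected] <- lam[otu_ids %in% affected] * effect_size
    counts[i, ] <- rmultinom(1, depth, lam / sum(lam))
  }
  list(otus = otu_data(labeled_matrix(counts, rownames(counts), otu_ids),
                       taxonomy),
       panel_taxa = panel_taxa,
       truth = list(group = setNames(group, rownames(counts)),
                    affected = affected, base_abundance = base,
                    seed = seed))
}

#' Simulate phenotype tables tied to a latent age variable
#'
#' Each of the eight clinical measurements equals its loading times a latent
#' age (standard normal) plus Gaussian noise; skin color evenness carries a
#' negative loading. Deterministic given `seed`.
#'
#' @param n_subjects number of subjects (default 50)
#' @param loadings named loadings per measurement (defaults to
#'   [DEFAULT_ORIENTATION], i.e. unit loadings, evenness negative)
#' @param noise_sd Gaussian noise standard deviation (default 0.5)
#' @param seed RNG seed
#' @return list with `phenotypes` (subjects x 8 data frame) and `truth`
#'   (`age`, `loadings`, `noise_sd`)
#' @export
simulate_phenotypes <- function(n_subjects = 50,
                                loadings = DEFAULT_ORIENTATION,
                                noise_sd = 0.5, seed = 1) {
  if (n_subjects < 3) stop("need at least 3 subjects")
  set.seed(seed)
  age <- rnorm(n_subjects)
  subj <- sprintf("S%03d", seq_len(n_subjects))
  m <- vapply(PHENO_MEASUREMENTS, function(p)
    loadings[[p]] * age + rnorm(n_subjects, 0, noise_sd),
    numeric(n_subjects))
  rownames(m) <- subj
  list(phenotypes = as.data.frame(m),
       truth = list(age = setNames(age, subj), loadings = loadings,
                    noise_sd = noise_sd, seed = seed))
}
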