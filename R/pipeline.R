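# Orchestration: the ortho -> msa -> phmm -> calibrate chain as one helper,
# and a deterministic end-to-end pipeline over the synthetic world with
# provenance headers and a run manifest. Rerunning with an identical config
# reproduces byte-identical outputs.

#' Build and calibrate profile HMMs for a proteome panel
#'
#' Chains orthology inference, progressive alignment, profile construction
#' and GA calibration: similarity graph, RBH orthogroups, one alignment and
#' model per selected group, each calibrated with its members as true
#' positives and all other panel proteins as true negatives.
#'
#' @param proteins protein record data frame (the reference panel)
#' @param groups_to_model `"multi"` models every orthogroup with >= 2
#'   members, `"seed"` only groups flagged by the seed-gene table, `"all"`
#'   every group (singletons cannot be aligned and are skipped with a
#'   warning)
#' @param seed_genes optional seed-gene table (see [read_seed_genes()])
#' @param min_norm_score similarity-graph retention threshold
#' @param pseudocount emission pseudocount for [build_profile()]
#' @param max_gap_frac match-column cutoff for [select_match_columns()]
#' @param name_fun optional `function(member_ids) -> model name`; defaults to
#'   the orthogroup id
#' @return list: `models` (calibrated, named), `groups`, `edges`,
#'   `alignments`, `scores` (panel score matrix)
#' @export
build_panel_models <- function(proteins, groups_to_model = c("multi", "seed", "all"),
                               seed_genes = NULL, min_norm_score = 0.3,
                               pseudocount = 1, max_gap_frac = 0.5,
                               name_fun = NULL) {
  groups_to_model <- match.arg(groups_to_model)
  edges <- build_similarity_graph(proteins, min_norm_score = min_norm_score)
  groups <- cluster_orthogroups(edges, proteins, seed_genes)
  sizes <- table(groups$group_id)
  gsel <- switch(groups_to_model,
    multi = names(sizes)[sizes >= 2],
    seed = unique(groups$group_id[groups$is_seed_group]),
    all = names(sizes))
  small <- gsel[sizes[gsel] < 2]
  if (length(small)) {
    warning("skipping singleton group(s): ", paste(small, collapse = ", "))
    gsel <- setdiff(gsel, small)
  }
  if (!length(gsel)) stop("no orthogroups eligible for modeling")
  bg <- aa_background(proteins)
  alignments <- list()
  models <- list()
  for (gid in sort(gsel)) {
    mem <- groups$protein_id[groups$group_id == gid]
    seqs <- proteins[proteins$protein_id %in% mem, , drop = FALSE]
    aln <- progressive_align(seqs)
    alignments[[gid]] <- aln
    nm <- if (is.null(name_fun)) gid else name_fun(mem)
    models[[nm]] <- build_profile(aln, pseudocount = pseudocount,
                                  background = bg, name = nm,
                                  match_flags = select_match_columns(aln, max_gap_frac))
  }
  scores <- score_matrix(models, proteins)
  for (nm in names(models)) {
    mem <- models[[nm]]$members
    pos <- proteins[proteins$protein_id %in% mem, , drop = FALSE]
    neg <- proteins[!proteins$protein_id %in% mem, , drop = FALSE]
    models[[nm]] <- calibrate_ga(models[[nm]], pos, neg,
                                 scores = scores[, nm])
  }
  list(models = models, groups = groups, edges = edges,
       alignments = alignments, scores = scores)
}

.default_config <- function() {
  list(
    out_dir = "skincomet_run",
    seed = 17,
    panel = list(n_genomes = 10, n_families = 12, n_decoys = 8,
                 seq_length = 250, sub_rate = 0.15),
    models = list(min_norm_score = 0.3, pseudocount = 1, max_gap_frac = 0.5),
    community = list(n_samples = 50, effect_size = 3, n_affected = 3,
                     depth = 10000),
    phenotypes = list(noise_sd = 0.5),
    rda = list(transform = "hellinger", n_perm = 999, top_k_otu = 20,
               top_k_gene = 15)
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown keys (a `skincomet_config_error`).
#' @param config nested list, or path to a JSON file
#' @return validated config list
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  def <- .default_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad))
    stop(structure(class = c("skincomet_config_error", "error", "condition"),
                   list(message = paste("unknown config key(s):",
                                        paste(bad, collapse = ", ")),
                        call = NULL)))
  for (k in names(config)) {
    if (is.list(def[[k]])) {
      badk <- setdiff(names(config[[k]]), names(def[[k]]))
      if (length(badk))
        stop(structure(class = c("skincomet_config_error", "error", "condition"),
                       list(message = paste0("unknown config key(s) under ", k,
                                             ": ", paste(badk, collapse = ", ")),
                            call = NULL)))
      def[[k]][names(config[[k]])] <- config[[k]]
    } else def[[k]] <- config[[k]]
  }
  def
}

.config_hash <- function(config) {
  config$out_dir <- NULL  # hash the scientific parameters, not the location
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the end-to-end pipeline on the synthetic world
#'
#' Simulates a reference panel, builds and calibrates the model collection,
#' scans the genomes, simulates a two-group 16S community and phenotypes,
#' infers gene content from the OTU table, computes the SA score, runs RDA at
#' OTU and gene level, fits per-pathway linear models over a synthetic
#' catalog (planted families grouped into pathways), and writes the
#' heatmap-ready pathway table. Every output TSV carries a provenance header
#' (config hash, seed, stage); a `manifest.json` summarizes the run.
#'
#' @param config nested list or JSON path, see [validate_config()]
#' @param stages ordered subset of
#'   `c("panel", "models", "scan", "community", "infer", "phenotypes",
#'   "stats")`; later stages require the artifacts of earlier ones in memory,
#'   so prefixes of the full vector are the supported subsets
#' @return (invisibly) list of artifact paths and in-memory results
#' @export
run_pipeline <- function(config = list(),
                         stages = c("panel", "models", "scan", "community",
                                    "infer", "phenotypes", "stats")) {
  cfg <- validate_config(config)
  all_stages <- c("panel", "models", "scan", "community", "infer",
                  "phenotypes", "stats")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- function(s, obj, what) {
    if (is.null(obj))
      stop("stage '", s, "' requires missing artifact: ", what)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(cfg)
  prov <- function(stage) c(paste("config", hash), paste("seed", cfg$seed),
                            paste("stage", stage),
                            paste("skincomet",
                                  as.character(utils::packageVersion("skincomet"))))
  out <- list(paths = character(0))
  t0 <- Sys.time()
  log_stage <- function(s, n) message(sprintf(
    "[skincomet] %-10s %5d records  %6.1fs", s, n,
    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  emit <- function(m, name, stage) {
    p <- file.path(cfg$out_dir, name)
    write_matrix_tsv(m, p, header_comments = prov(stage))
    out$paths <<- c(out$paths, p)
  }

  if ("panel" %in% stages) {
    out$panel <- do.call(simulate_panel, c(cfg$panel, list(seed = cfg$seed)))
    p <- file.path(cfg$out_dir, "panel.faa")
    write_fasta(out$panel$proteins, p)
    out$paths <- c(out$paths, p)
    log_stage("panel", nrow(out$panel$proteins))
  }
  if ("models" %in% stages) {
    need("models", out$panel, "panel proteins")
    truth_members <- out$panel$truth$members
    name_fun <- function(mem) {
      hit <- truth_members$model[match(mem, truth_members$protein_id)]
      hit <- hit[!is.na(hit)]
      if (length(hit)) names(sort(table(hit), decreasing = TRUE))[1]
      else paste(sort(mem), collapse = "+")
    }
    out$built <- build_panel_models(
      out$panel$proteins, groups_to_model = "multi",
      min_norm_score = cfg$models$min_norm_score,
      pseudocount = cfg$models$pseudocount,
      max_gap_frac = cfg$models$max_gap_frac, name_fun = name_fun)
    p <- file.path(cfg$out_dir, "models.hmm")
    write_model_file(out$built$models, p)
    out$paths <- c(out$paths, p)
    # panel tree from the single-copy core, when one exists
    core <- single_copy_core(out$built$groups,
                             unique(out$panel$proteins$genome_id))
    if (length(unique(core$group_id)) >= 1 &&
        length(unique(out$panel$proteins$genome_id)) >= 3) {
      aln_g <- lapply(split(core, core$group_id), function(cg) {
        a <- out$built$alignments[[cg$group_id[1]]]
        msa(cg$genome_id[match(a$row_ids, cg$protein_id)], a$rows)
      })
      d <- concat_core_distances(core, aln_g)
      writeLines(nj_tree(d), file.path(cfg$out_dir, "panel_tree.nwk"))
      out$paths <- c(out$paths, file.path(cfg$out_dir, "panel_tree.nwk"))
    }
    log_stage("models", length(out$built$models))
  }
  if ("scan" %in% stages) {
    need("scan", out$built, "calibrated models")
    out$genome_counts <- scan_genomes(out$built$models, out$panel$proteins)
    emit(out$genome_counts, "genome_model_counts.tsv", "scan")
    log_stage("scan", nrow(out$genome_counts))
  }
  if ("community" %in% stages) {
    need("community", out$panel, "panel")
    out$community <- do.call(simulate_community, c(
      list(genomes = unique(out$panel$proteins$genome_id)),
      cfg$community, list(seed = cfg$seed + 1L)))
    emit(out$community$otus$counts, "otu_counts.tsv", "community")
    log_stage("community", nrow(out$community$otus$counts))
  }
  if ("infer" %in% stages) {
    need("infer", out$community, "community OTU table")
    need("infer", out$genome_counts, "genome scan counts")
    mapping <- map_otus_to_genomes(out$community$otus, out$community$panel_taxa)
    rel <- renorm_sample_relative(out$community$otus$counts)
    rel_otus <- otu_data(.set_norm_state(rel, "raw_counts"),
                         out$community$otus$taxonomy)
    out$gene_pred <- predict_gene_content(rel_otus, out$genome_counts, mapping)
    emit(out$gene_pred, "predicted_gene_content.tsv", "infer")
    log_stage("infer", nrow(out$gene_pred))
  }
  if ("phenotypes" %in% stages) {
    need("phenotypes", out$community, "community (sample ids)")
    n <- nrow(out$community$otus$counts)
    out$pheno <- do.call(simulate_phenotypes, c(
      list(n_subjects = n), cfg$phenotypes, list(seed = cfg$seed + 2L)))
    rownames(out$pheno$phenotypes) <- rownames(out$community$otus$counts)
    names(out$pheno$truth$age) <- rownames(out$community$otus$counts)
    emit(labeled_matrix(as.matrix(out$pheno$phenotypes) -
                          min(out$pheno$phenotypes),
                        rownames(out$pheno$phenotypes),
                        colnames(out$pheno$phenotypes)),
         "phenotypes_shifted.tsv", "phenotypes")
    log_stage("phenotypes", n)
  }
  if ("stats" %in% stages) {
    need("stats", out$pheno, "phenotype table")
    need("stats", out$gene_pred, "predicted gene content")
    sa <- compute_sa_score(out$pheno$phenotypes)
    out$sa <- sa
    grp <- as.integer(out$community$truth$group == "old")
    out$rda_otu <- rda(out$community$otus$counts, grp,
                       transform = cfg$rda$transform,
                       n_perm = cfg$rda$n_perm, seed = cfg$seed + 3L)
    out$rda_gene <- rda(out$gene_pred, sa[rownames(out$gene_pred)],
                        transform = cfg$rda$transform,
                        n_perm = cfg$rda$n_perm, seed = cfg$seed + 4L)
    # synthetic catalog: planted families grouped into pathways of 3
    fams <- colnames(out$genome_counts)
    sc <- data.frame(pathway = paste0("SynthPathway", (seq_along(fams) - 1) %/% 3 + 1),
                     module_id = paste0("synmod", (seq_along(fams) - 1) %/% 3 + 1),
                     model_name = fams, stringsAsFactors = FALSE)
    class(sc) <- c("module_catalog", "data.frame")
    pw <- pathway_scores(out$gene_pred, sc)
    out$pathway_lm <- pathway_lm(pw, sa, fdr = TRUE)
    lm_m <- labeled_matrix(
      pmax(as.matrix(out$pathway_lm[, c("r2", "p_value", "q_value")]), 0),
      out$pathway_lm$pathway, c("r2", "p_value", "q_value"))
    emit(lm_m, "pathway_lm.tsv", "stats")
    out$fig_table <- fig_pathway_table(pw, sa)
    emit(out$fig_table, "pathway_heatmap.tsv", "stats")
    arr <- top_arrows(out$rda_otu, min(cfg$rda$top_k_otu,
                                       length(out$rda_otu$arrow_scores)))
    emit(labeled_matrix(abs(matrix(arr$arrow_score, ncol = 1,
                                   dimnames = list(arr$variable, "abs_arrow"))),
                        arr$variable, "abs_arrow"),
         "rda_otu_top_arrows.tsv", "stats")
    log_stage("stats", nrow(out$pathway_lm))
  }
  manifest <- list(config = cfg, config_hash = hash,
                   outputs = out$paths,
                   versions = list(skincomet =
                     as.character(utils::packageVersion("skincomet"))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(cfg$out_dir, "manifest.json"))
  invisible(out)
}
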