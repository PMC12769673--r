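#' Default configuration for a synthetic screen pipeline run
#'
#' Mirrors the screen design the package emulates: four arms (EtOH solvent
#' reference, ACT, CAP, ACTCAP), three replicates, 15 days with 72-h
#' passages, a 4e7-cell bottleneck, about 150x sequencing coverage and a
#' Z-difference hit threshold of 3. The default library is deliberately
#' small (desk scale); raise \code{n_genes} for genome-scale runs.
#'
#' @param n_genes,guides_per_gene,n_controls library dimensions.
#' @param seed master seed; every stage derives its own child seed from it.
#' @return nested configuration list.
#' @export
default_screen_config <- function(n_genes = 1000L, guides_per_gene = 4L,
                                  n_controls = 100L, seed = 1L) {
  list(
    version = 1L,
    seed = as.integer(seed),
    library = list(n_genes = n_genes, guides_per_gene = guides_per_gene,
                   n_controls = n_controls),
    design = list(conditions = c("ETOH", "ACT", "CAP", "ACTCAP"),
                  reference = "ETOH", n_replicates = 3L, duration_days = 15,
                  passage_interval_h = 72, bottleneck_cells = 4e7,
                  untreated_doubling_time_h = 24,
                  growth_inhibition = list(ACT = 0.40, CAP = 0.40, ACTCAP = 0.40),
                  reads_per_sample = NULL),
    fitness = list(class_spec = list(ACT = list(n_suppressors = 50L,
                                                n_sick = 50L,
                                                s_suppressor = 0.4,
                                                s_sick = -0.4)),
                   shared_sick_genes = 20L, s_shared_sick = -0.4),
    scoring = list(contrasts = list(c("ACT", "ETOH"), c("ACT", "ACTCAP")),
                   threshold = 3, pseudocount = 0.5,
                   normalization = "total", z_before_average = FALSE),
    enrichment = list(gene_sets = NULL, min_set_size = 3L)
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in \code{\link{default_screen_config}}.
#'   Missing keys fall back to defaults.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  modifyList(default_screen_config(), user)
}

validate_config <- function(config) {
  d <- config$design
  if (!d$reference %in% d$conditions) {
    stop_("config: reference '%s' not among conditions", d$reference)
  }
  for (ct in config$scoring$contrasts) {
    bad <- setdiff(unlist(ct), d$conditions)
    if (length(bad)) stop_("config: contrast references undeclared condition(s): %s",
                           paste(bad, collapse = ", "))
  }
  bad <- setdiff(names(config$fitness$class_spec), d$conditions)
  if (length(bad)) stop_("config: class_spec references undeclared condition(s): %s",
                         paste(bad, collapse = ", "))
  invisible(config)
}

config_design <- function(config) {
  d <- config$design
  screen_design(conditions = d$conditions, reference = d$reference,
                n_replicates = d$n_replicates, duration_days = d$duration_days,
                passage_interval_h = d$passage_interval_h,
                bottleneck_cells = d$bottleneck_cells,
                reads_per_sample = d$reads_per_sample,
                untreated_doubling_time_h = d$untreated_doubling_time_h,
                growth_inhibition = unlist(d$growth_inhibition))
}

#' Run the synthetic screen pipeline end to end
#'
#' Simulator -> counts -> scoring -> hit calling -> (optional) gene-set
#' enrichment, with every output written under \code{out_dir} and a run
#' manifest (config echo, stage seeds, record counts, MD5 checksum per
#' file). Identical config + seed reproduce byte-identical outputs. A stage
#' failure aborts the run, removes partial outputs and names the stage.
#'
#' @param config configuration list (see \code{\link{default_screen_config}})
#'   or path to a YAML file.
#' @param out_dir output directory, created if needed.
#' @return invisible list with the in-memory stage results
#'   (\code{library}, \code{truth}, \code{trajectory}, \code{counts},
#'   \code{fit}, \code{hits}, \code{enrichment}, \code{manifest}).
#' @export
run_screen_pipeline <- function(config = default_screen_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  on.exit({
    if (stage != "done") {
      unlink(written)
      message(sprintf("pipeline aborted at stage '%s'; partial outputs removed",
                      stage))
    }
  })
  emit <- function(writer, file) {
    path <- file.path(out_dir, file)
    writer(path)
    written <<- c(written, path)
    path
  }
  seed <- config$seed

  stage <- "library"
  lib <- build_library(config$library$n_genes, config$library$guides_per_gene,
                       config$library$n_controls,
                       seed = child_seed(seed, "library"))
  emit(function(p) write_library_tsv(lib, p), "library.tsv")

  stage <- "fitness"
  design <- config_design(config)
  truth <- assign_fitness(lib, design, config$fitness$class_spec,
                          shared_sick_genes = config$fitness$shared_sick_genes %||% 0L,
                          s_shared_sick = config$fitness$s_shared_sick %||% -0.4,
                          seed = child_seed(seed, "fitness"))
  emit(function(p) jsonlite::write_json(
    list(gene_class = as.data.frame(truth$gene_class),
         s = as.data.frame(truth$s),
         guide_efficacy = as.list(truth$guide_efficacy),
         seeds = list(master = seed,
                      fitness = child_seed(seed, "fitness"))),
    p, auto_unbox = TRUE, digits = NA), "truth.json")

  stage <- "passaging"
  traj <- simulate_passaging(lib, truth, design,
                             seed = child_seed(seed, "passaging"))

  stage <- "sequencing"
  tab <- sample_counts(traj, design, seed = child_seed(seed, "sequencing"))
  emit(function(p) write_counts_tsv(tab, p), "counts.tsv")
  emit(function(p) write_tsv_(tab$samples, p), "samples.tsv")

  stage <- "scoring"
  fit <- score_screen(tab, lib, contrasts = config$scoring$contrasts,
                      pseudocount = config$scoring$pseudocount,
                      normalization = config$scoring$normalization,
                      z_before_average = isTRUE(config$scoring$z_before_average))
  gs <- data.frame(gene = rownames(fit$z), fit$gene_lfc, z = fit$z,
                   check.names = TRUE, stringsAsFactors = FALSE)
  emit(function(p) write_tsv_(gs, p), "gene_scores.tsv")

  stage <- "hits"
  hits <- list()
  for (ct in colnames(fit$delta_z)) {
    emit(function(p) export_sigma_table(fit, ct, p,
                                        threshold = config$scoring$threshold),
         paste0("sigma_", ct, ".tsv"))
    h <- call_hits(fit$delta_z[, ct], config$scoring$threshold, contrast = ct)
    hits[[ct]] <- h
    emit(function(p) write_tsv_(h, p), paste0("hits_", ct, ".tsv"))
  }

  stage <- "enrichment"
  enr <- NULL
  sets <- config$enrichment$gene_sets
  if (!is.null(sets)) {
    if (is.character(sets)) sets <- read_gmt(sets)
    ct1 <- colnames(fit$delta_z)[1]
    sup <- hits[[ct1]]$gene[hits[[ct1]]$direction == "suppressor"]
    if (length(sup)) {
      enr <- enrich_sets(sup, rownames(fit$z), sets,
                         min_set_size = config$enrichment$min_set_size)
      emit(function(p) write_tsv_(enr, p), "enrichment.tsv")
    }
  }

  stage <- "manifest"
  manifest <- list(
    config = config,
    seeds = lapply(stats::setNames(nm = c("library", "fitness", "passaging",
                                          "sequencing")),
                   function(tag) child_seed(seed, tag)),
    n_guides = nrow(lib), n_genes = nrow(fit$z),
    n_samples = ncol(tab$counts),
    conditions = design$conditions, n_replicates = design$n_replicates,
    files = lapply(stats::setNames(nm = basename(written)), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    })
  )
  emit(function(p) jsonlite::write_json(manifest, p, auto_unbox = TRUE,
                                        digits = NA, pretty = TRUE),
       "manifest.json")
  stage <- "done"
  invisible(list(library = lib, truth = truth, trajectory = traj,
                 counts = tab, fit = fit, hits = hits, enrichment = enr,
                 manifest = manifest))
}

#' Run the isotope-tracing pipeline
#'
#' Either loads a measured isotopologue CSV or simulates a grid of
#' oxidative-PPP flux fractions, then applies natural-abundance / purity
#' correction, total-intensity normalization and QC, and reports the
#' lactate m+1/m+2 PPP index (and, where present, the G6P/glucose uptake
#' index) per replicate. QC exclusions are recorded in the manifest.
#'
#' @param mid_csv path to a MID CSV (see \code{\link{read_mid_csv}});
#'   \code{NULL} simulates instead.
#' @param f_ppp_grid PPP flux fractions to simulate when no CSV is given.
#' @param tracer a \code{\link{tracer_spec}}.
#' @param noise_sd,n_replicates simulation parameters.
#' @param qc_min_fraction total-intensity QC threshold (fraction of batch
#'   median); flagged replicates are excluded and logged.
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return invisible list with \code{ratios} (per f / replicate PPP and
#'   uptake indices), \code{corrected} MID fractions, \code{excluded}
#'   sample keys and \code{manifest}.
#' @export
run_tracing_pipeline <- function(mid_csv = NULL,
                                 f_ppp_grid = seq(0.1, 0.9, by = 0.1),
                                 tracer = tracer_spec(), noise_sd = 0,
                                 n_replicates = 1L, qc_min_fraction = 0.5,
                                 out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(mid_csv)) {
    mids <- read_mid_csv(mid_csv)
    if (!"f_ppp" %in% names(mids)) mids$f_ppp <- 0
    if (!"replicate" %in% names(mids)) mids$replicate <- 1L
    input <- mid_csv
  } else {
    mids <- do.call(rbind, lapply(f_ppp_grid, function(f) {
      df <- simulate_labeling(f, tracer, noise_sd = noise_sd,
                              n_replicates = n_replicates,
                              seed = child_seed(seed, sprintf("f%.3f", f)))
      df$f_ppp <- f
      df
    }))
    input <- "simulated"
    write_mid_csv(mids, file.path(out_dir, "mids_raw.csv"))
  }
  mcols <- grep("^m[0-9]+$", names(mids), value = TRUE)
  key <- interaction(mids$f_ppp, mids$replicate, drop = TRUE)
  totals <- tapply(rowSums(mids[, mcols], na.rm = TRUE), key, sum)
  excluded <- names(totals)[qc_low_yield(as.numeric(totals), qc_min_fraction)]
  if (length(excluded)) {
    message("QC: excluding low-yield replicate(s): ",
            paste(excluded, collapse = ", "))
  }
  keep <- !(as.character(key) %in% excluded)
  mids <- mids[keep, , drop = FALSE]

  rows <- list(); corrected <- list()
  for (i in seq_len(nrow(mids))) {
    x <- as.numeric(mids[i, mcols])
    x <- x[!is.na(x)]
    M <- correction_matrix(length(x) - 1L, tracer$p13, tracer$purity)
    cm <- correct_mid(x, M)
    corrected[[i]] <- data.frame(
      f_ppp = mids$f_ppp[i], replicate = mids$replicate[i],
      metabolite = mids$metabolite[i],
      isotopologue = paste0("m", seq_along(cm$fractions) - 1L),
      fraction = cm$fractions, total = cm$raw_total,
      stringsAsFactors = FALSE)
  }
  corrected <- do.call(rbind, corrected)
  for (grp in split(corrected,
                    interaction(corrected$f_ppp, corrected$replicate,
                                drop = TRUE))) {
    lac <- grp[grp$metabolite == "lactate", ]
    g6p <- grp[grp$metabolite == "g6p", ]
    glc <- grp[grp$metabolite == "glucose", ]
    rows[[length(rows) + 1L]] <- data.frame(
      f_ppp = grp$f_ppp[1], replicate = grp$replicate[1],
      ppp_index = if (nrow(lac)) ppp_index(lac$fraction) else NA_real_,
      m1_frac_labeled = if (nrow(lac)) {
        lac$fraction[2] / (lac$fraction[2] + lac$fraction[3])
      } else NA_real_,
      uptake_index = if (nrow(g6p) && nrow(glc)) {
        uptake_index(g6p$total[1], glc$total[1])
      } else NA_real_,
      stringsAsFactors = FALSE)
  }
  ratios <- do.call(rbind, rows)
  ratios <- ratios[order(ratios$f_ppp, ratios$replicate), , drop = FALSE]
  rownames(ratios) <- NULL
  write_tsv_(corrected, file.path(out_dir, "corrected_mids.tsv"))
  write_tsv_(ratios, file.path(out_dir, "ratios.tsv"))
  files <- c("corrected_mids.tsv", "ratios.tsv")
  if (is.null(mid_csv)) files <- c("mids_raw.csv", files)
  manifest <- list(input = input, seed = seed,
                   tracer = unclass(tracer), noise_sd = noise_sd,
                   qc_min_fraction = qc_min_fraction,
                   excluded = as.list(excluded),
                   files = lapply(stats::setNames(nm = files), function(f) {
                     unname(tools::md5sum(file.path(out_dir, f)))
                   }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(ratios = ratios, corrected = corrected,
                 excluded = excluded, manifest = manifest))
}
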