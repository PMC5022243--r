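#' Run the full genomic-prediction analysis pipeline
#'
#' Orchestrates simulate (or load) -> quality control -> model fitting ->
#' variance decomposition -> model comparison -> hold-out validation into one
#' reproducible run. Every stage's outputs are written before the next stage
#' begins; a failure leaves earlier outputs intact together with a partial
#' manifest.
#'
#' The configuration is a list (or path to a YAML file) with entries:
#' \describe{
#'   \item{genotypes/phenotypes}{paths to a phased VCF and phenotype TSV, or}
#'   \item{simulate}{a list of [sim_config()] arguments (used when paths are
#'     absent); `simulate_only: true` stops after writing the fixtures}
#'   \item{models}{character vector among `"A"`, `"AD"`, `"AI"`, `"ADI"`
#'     (default all four; model A is added if absent, as the baseline)}
#'   \item{chain_length, burn_in, thinning, mixing_proportions}{chain control
#'     passed to [model_spec()]}
#'   \item{cutoff_date}{train/validation split date (defaults to the simulated
#'     population's cutoff)}
#'   \item{seed}{global seed; per-stage seeds are derived from it}
#' }
#'
#' Design matrices are always built with training-set allele frequencies, and
#' models are fitted on the training individuals; variance decompositions,
#' pseudo Bayes factors (CPOs on training observations) and validation
#' reliabilities/bias all come from those fits.
#'
#' @param config List or path to a YAML configuration file.
#' @param out_dir Output directory; refuses to overwrite a completed run
#'   unless `overwrite = TRUE`.
#' @param overwrite Allow writing into a directory holding a finished run.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.yaml`.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (file.exists(file.path(out_dir, "manifest.yaml")) && !overwrite) {
    stop("output directory holds a completed run; use overwrite = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stage_seed <- function(k) (seed * 1000L + k) %% .Machine$integer.max

  manifest <- list(config = config, seed = seed,
                   package_version = as.character(packageVersion("imprintgp")),
                   started = format(Sys.time()), stages = list())
  write_manifest <- function() {
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.partial.yaml"))
  }
  timed <- function(name, fn) {
    t0 <- Sys.time()
    out <- fn()
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    write_manifest()
    out
  }

  # --- stage 1: obtain data ------------------------------------------------
  cutoff <- config$cutoff_date
  dat <- timed("data", function() {
    if (!is.null(config$genotypes)) {
      geno <- read_phased_vcf(config$genotypes)
      pheno <- read_phenotypes(config$phenotypes, geno)
      list(genotypes = geno, phenotypes = pheno)
    } else {
      cfg <- do.call(sim_config, utils::modifyList(
        config$simulate %||% list(), list(seed = stage_seed(1L))))
      pop <- simulate_population(cfg)
      files <- write_population(pop, file.path(out_dir, "simulated"))
      if (is.null(cutoff)) cutoff <<- pop$cutoff_date
      list(genotypes = pop$genotypes, phenotypes = pop$phenotypes,
           files = files)
    }
  })
  if (isTRUE(config$simulate_only)) {
    manifest$finished <- format(Sys.time())
    manifest$outputs <- list.files(out_dir)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    return(invisible(manifest))
  }
  if (is.null(cutoff)) stop("cutoff_date is required with file inputs")

  # --- stage 2: QC ---------------------------------------------------------
  qc <- timed("qc", function() {
    res <- qc_filter(dat$genotypes)
    write.table(as.data.frame(res$report), file.path(out_dir, "qc_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  geno <- qc$genotypes
  pheno <- dat$phenotypes |>
    dplyr::filter(.data$sample_id %in% geno$sample_ids)

  # --- stage 3: split and design matrices (training frequencies) -----------
  split <- split_by_date(pheno, cutoff)
  train_geno <- geno[match(split$train$sample_id, geno$sample_ids), ]
  val_geno <- geno[match(split$validation$sample_id, geno$sample_ids), ]
  train_freqs <- allele_frequency(train_geno)
  design_train <- design_matrices(train_geno, freqs = train_freqs)
  design_val <- design_matrices(val_geno, freqs = train_freqs)

  # --- stage 4: fit the models ---------------------------------------------
  models <- config$models %||% c("A", "AD", "AI", "ADI")
  models <- union("A", models)
  fits <- timed("fit", function() {
    out <- list()
    for (i in seq_along(models)) {
      spec <- model_spec(
        models[i],
        mixing_proportions = config$mixing_proportions %||%
          c(0.889, 0.1, 0.01, 0.001),
        chain_length = config$chain_length %||% 50000L,
        burn_in = config$burn_in %||% 20000L,
        thinning = config$thinning %||% 10L,
        seed = stage_seed(10L + i))
      fit <- fit_genomic_mixture(split$train, design_train, spec)
      write.table(as.data.frame(fit$snp_effects),
                  file.path(out_dir, paste0("snp_effects_", models[i], ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(as.data.frame(tidy(fit)),
                  file.path(out_dir, paste0("posterior_", models[i], ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      out[[models[i]]] <- fit
    }
    out
  })

  # --- stage 5: variance decomposition -------------------------------------
  decomps <- timed("decompose", function() {
    out <- purrr::imap(fits, function(f, nm) {
      d <- variance_decomposition(f)
      df <- as.data.frame(d)
      df$model <- nm
      df
    })
    tab <- dplyr::bind_rows(out)
    write.table(tab, file.path(out_dir, "variance_components.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    purrr::map(fits, variance_decomposition)
  })

  # --- stage 6: model comparison via pseudo Bayes factors ------------------
  comparison <- timed("compare", function() {
    tab <- purrr::map_dfr(names(fits), function(nm) {
      pbf <- pseudo_bayes_factor(fits[[nm]], fits[["A"]])
      tibble::tibble(model = nm, lpml = fits[[nm]]$lpml,
                     two_ln_k_vs_A = pbf$two_ln_k, evidence = pbf$evidence)
    })
    write.table(as.data.frame(tab), file.path(out_dir, "model_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })

  # --- stage 7: hold-out validation ----------------------------------------
  validation <- timed("validate", function() {
    dA <- decomps[["A"]]
    comp <- setNames(dA$estimate, dA$component)
    h2_yc <- h2_of_corrected_phenotype(comp["additive"], comp["litter"],
                                       comp["residual"])
    rep <- validate_predictions(fits, split$validation, design_val, h2_yc)
    write.table(as.data.frame(rep), file.path(out_dir, "validation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    rep
  })

  manifest$cutoff_date <- format(as.Date(cutoff))
  manifest$n_train <- nrow(split$train)
  manifest$n_validation <- nrow(split$validation)
  manifest$outputs <- list.files(out_dir)
  manifest$checksums <- as.list(tools::md5sum(
    file.path(out_dir, setdiff(manifest$outputs,
                               c("manifest.yaml", "manifest.partial.yaml")))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  manifest$finished <- format(Sys.time())
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  unlink(file.path(out_dir, "manifest.partial.yaml"))

  invisible(c(manifest,
              list(fits = fits, decompositions = decomps,
                   comparison = comparison, validation = validation)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
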