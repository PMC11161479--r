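#' Default pipeline configuration
#'
#' Returns the full configuration list with the standard defaults:
#' blending alpha = 0.95 / beta = 0.05, CT = 1.125 with exponent cap 5,
#' 3 weighting iterations, 1-Mb windows, top-10 windows, and the usual
#' 50K-chip QC thresholds.
#'
#' @param outdir output directory.
#' @param seed integer seed.
#' @return Nested configuration list (can be written/read as YAML).
#' @export
default_config <- function(outdir = "wssgwas_out", seed = 1) {
  list(
    paths = list(pedigree = NULL, phenotypes = NULL, genotypes = NULL,
                 outdir = outdir),
    simulate = list(enabled = TRUE),
    qc = list(min_ind_call_rate = 0.95, min_snp_call_rate = 0.95,
              min_maf = 0.05, min_hwe_p = 1e-6),
    model = list(fixed = c("sex", "birth_type", "herd", "birth_year",
                           "dam_age"),
                 trait = "trait"),
    reml = list(method = "ai", max_iter = 50, tol = 1e-3),
    gwas = list(alpha = 0.95, beta = 0.05, ct = 1.125, cap = 5,
                n_iter = 3, window_bp = 1e6, top_k = 10),
    seed = seed)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  merge_config(default_config(), config)
}

pipeline_inputs <- function(cfg) {
  if (isTRUE(cfg$simulate$enabled)) {
    sim_args <- cfg$simulate
    sim_args$enabled <- NULL
    if (!is.null(sim_args$vc)) sim_args$vc <- do.call(variance_components,
                                                      sim_args$vc)
    sim_args$seed <- sim_args$seed %||% cfg$seed
    scfg <- do.call(sim_config, sim_args)
    ds <- simulate_dataset(scfg)
    list(ped = ds$ped, phenos = ds$phenos, geno = ds$geno,
         truth = ds$truth)
  } else {
    p <- cfg$paths
    for (nm in c("pedigree", "phenotypes", "genotypes")) {
      if (is.null(p[[nm]])) stop("config paths$", nm, " is required")
    }
    list(ped = sort_pedigree(read_pedigree_csv(p$pedigree)),
         phenos = read_phenotypes_csv(p$phenotypes),
         geno = read_plink(p$genotypes),
         truth = NULL)
  }
}

#' Run the full WssGWAS pipeline
#'
#' Stages: simulate or ingest, SNP quality control, imputation, REML
#' variance components (pedigree-based), the iterative weighted single-step
#' GWAS, window variance decomposition and top-k selection.  All tabular
#' outputs are written under \code{paths$outdir}; re-running with the same
#' configuration and seed reproduces them byte for byte.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   to a YAML file of overrides.
#' @return (Invisibly) a list with the fitted objects: \code{qc},
#'   \code{vc}, \code{gwas}, \code{inputs}.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_config(config)
  outdir <- cfg$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[3]
  stage <- function(msg, ...) message(sprintf("[%6.1fs] %s",
                                              proc.time()[3] - t0,
                                              sprintf(msg, ...)))

  stage("reading inputs")
  inp <- pipeline_inputs(cfg)
  stage("pedigree: %d animals; phenotypes: %d records; genotypes: %d x %d",
        nrow(inp$ped), nrow(inp$phenos), nrow(inp$geno$counts),
        ncol(inp$geno$counts))

  thr <- qc_thresholds(cfg$qc$min_ind_call_rate, cfg$qc$min_snp_call_rate,
                       cfg$qc$min_maf, cfg$qc$min_hwe_p)
  qc <- apply_qc(inp$geno, thr)
  utils::write.table(qc$report, file.path(outdir, "qc_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  stage("QC: %d SNPs and %d individuals retained",
        ncol(qc$genotypes$counts), nrow(qc$genotypes$counts))

  geno <- impute_missing(qc$genotypes, seed = cfg$seed)
  stage("imputation done")

  ped <- sort_pedigree(inp$ped)
  a_inv <- build_A_inverse(ped)
  design <- build_design(inp$phenos, ped, fixed = cfg$model$fixed,
                         trait = cfg$model$trait)
  vc <- estimate_varcomps_reml(design, a_inv, method = cfg$reml$method,
                               max_iter = cfg$reml$max_iter,
                               tol = cfg$reml$tol)
  utils::write.table(
    data.frame(component = c("sigma2_a", "sigma2_m", "sigma2_p", "sigma2_e"),
               estimate = c(vc$sigma2_a, vc$sigma2_m, vc$sigma2_p,
                            vc$sigma2_e)),
    file.path(outdir, "varcomps.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  stage("REML: a=%.4g m=%.4g pe=%.4g e=%.4g (%d iters)",
        vc$sigma2_a, vc$sigma2_m, vc$sigma2_p, vc$sigma2_e, vc$iterations)

  gw <- cfg$gwas
  fit <- run_wssgwas(inp$phenos, ped, geno, vc, n_iter = gw$n_iter,
                     alpha = gw$alpha, beta = gw$beta, ct = gw$ct,
                     cap = gw$cap, window_bp = gw$window_bp,
                     top_k = gw$top_k, fixed = cfg$model$fixed,
                     trait = cfg$model$trait)
  wd <- fit$windows_direct; wd$effect_type <- "direct"
  wm <- fit$windows_maternal; wm$effect_type <- "maternal"
  all_w <- rbind(wd, wm)
  all_w$top <- FALSE
  all_w$top[all_w$effect_type == "direct"][
    match(interaction(fit$top_direct$chr, fit$top_direct$window_start),
          interaction(wd$chr, wd$window_start))] <- TRUE
  all_w$top[all_w$effect_type == "maternal"][
    match(interaction(fit$top_maternal$chr, fit$top_maternal$window_start),
          interaction(wm$chr, wm$window_start))] <- TRUE
  write_windows_tsv(all_w, file.path(outdir, "windows.tsv"))
  write_snp_effects_tsv(fit$snp_effects,
                        file.path(outdir, "snp_effects.tsv"))
  sols <- rbind(
    data.frame(effect_type = "fixed", level_or_animal = names(fit$iterations[[gw$n_iter]]$fit$fixed),
               estimate = unname(fit$iterations[[gw$n_iter]]$fit$fixed)),
    data.frame(effect_type = "direct",
               level_or_animal = names(fit$iterations[[gw$n_iter]]$fit$a_hat),
               estimate = unname(fit$iterations[[gw$n_iter]]$fit$a_hat)),
    data.frame(effect_type = "maternal",
               level_or_animal = names(fit$iterations[[gw$n_iter]]$fit$m_hat),
               estimate = unname(fit$iterations[[gw$n_iter]]$fit$m_hat)),
    data.frame(effect_type = "pe",
               level_or_animal = names(fit$iterations[[gw$n_iter]]$fit$p_hat),
               estimate = unname(fit$iterations[[gw$n_iter]]$fit$p_hat)))
  utils::write.table(sols, file.path(outdir, "solutions.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  stage("top-10 direct windows explain %.2f%% of sigma2_a; maternal %.2f%% of sigma2_m",
        sum(fit$top_direct$pct_variance), sum(fit$top_maternal$pct_variance))
  invisible(list(qc = qc, vc = vc, gwas = fit, inputs = inp, config = cfg))
}

#' Command-line interface
#'
#' Subcommands: \code{simulate} (write a synthetic dataset),
#' \code{qc}, \code{reml}, \code{gwas}, \code{windows} (stage-wise runs) and
#' \code{full} (the whole pipeline).  All take \code{--config <yaml>} and
#' optionally \code{--out <dir>}; \code{simulate} and \code{full} take
#' \code{--seed <int>}.
#'
#' @param args character vector of command-line arguments (default
#'   \code{commandArgs(trailingOnly = TRUE)}).
#' @return Integer exit status, invisibly (0 = success, 2 = bad usage or
#'   missing input).
#' @export
wss_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: wssgwas <simulate|qc|reml|gwas|windows|full> [--config FILE] [--out DIR] [--seed INT]"
  fail <- function(msg, status = 2L) {
    message(msg)
    return(invisible(status))
  }
  if (length(args) < 1L) return(fail(usage))
  cmd <- args[1]
  if (!cmd %in% c("simulate", "qc", "reml", "gwas", "windows", "full"))
    return(fail(paste0("unknown subcommand '", cmd, "'\n", usage)))
  opt <- list(config = NULL, out = NULL, seed = NULL)
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% names(opt) || i == length(rest))
      return(fail(paste0("bad option '", rest[i], "'\n", usage)))
    opt[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  status <- tryCatch({
    cfg <- load_config(opt$config %||% list())
    if (!is.null(opt$out)) cfg$paths$outdir <- opt$out
    if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
    outdir <- cfg$paths$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (cmd == "full") {
      run_pipeline(cfg)
    } else if (cmd == "simulate") {
      sim_args <- cfg$simulate
      sim_args$enabled <- NULL
      sim_args$seed <- sim_args$seed %||% cfg$seed
      ds <- simulate_dataset(do.call(sim_config, sim_args))
      write_pedigree_csv(ds$ped, file.path(outdir, "pedigree.csv"))
      write_phenotypes_csv(ds$phenos, file.path(outdir, "phenotypes.csv"))
      write_plink_text(ds$geno, file.path(outdir, "genotypes"))
      utils::write.table(
        data.frame(animal = names(ds$truth$true_a),
                   true_a = unname(ds$truth$true_a),
                   true_m = unname(ds$truth$true_m)),
        file.path(outdir, "truth.tsv"), sep = "\t", row.names = FALSE,
        quote = FALSE)
      message("simulated dataset written to ", outdir)
    } else {
      inp <- pipeline_inputs(cfg)
      thr <- qc_thresholds(cfg$qc$min_ind_call_rate,
                           cfg$qc$min_snp_call_rate,
                           cfg$qc$min_maf, cfg$qc$min_hwe_p)
      qc <- apply_qc(inp$geno, thr)
      utils::write.table(qc$report, file.path(outdir, "qc_report.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      if (cmd == "qc") {
        message("QC report written to ", file.path(outdir, "qc_report.tsv"))
      } else {
        geno <- impute_missing(qc$genotypes, seed = cfg$seed)
        ped <- sort_pedigree(inp$ped)
        design <- build_design(inp$phenos, ped, fixed = cfg$model$fixed,
                               trait = cfg$model$trait)
        vc <- estimate_varcomps_reml(design, build_A_inverse(ped),
                                     method = cfg$reml$method,
                                     max_iter = cfg$reml$max_iter,
                                     tol = cfg$reml$tol)
        utils::write.table(
          data.frame(component = c("sigma2_a", "sigma2_m", "sigma2_p",
                                   "sigma2_e"),
                     estimate = c(vc$sigma2_a, vc$sigma2_m, vc$sigma2_p,
                                  vc$sigma2_e)),
          file.path(outdir, "varcomps.tsv"), sep = "\t",
          row.names = FALSE, quote = FALSE)
        if (cmd == "reml") {
          message("variance components written to ",
                  file.path(outdir, "varcomps.tsv"))
        } else {
          gw <- cfg$gwas
          fit <- run_wssgwas(inp$phenos, ped, geno, vc,
                             n_iter = gw$n_iter, alpha = gw$alpha,
                             beta = gw$beta, ct = gw$ct, cap = gw$cap,
                             window_bp = gw$window_bp, top_k = gw$top_k,
                             fixed = cfg$model$fixed,
                             trait = cfg$model$trait)
          write_snp_effects_tsv(fit$snp_effects,
                                file.path(outdir, "snp_effects.tsv"))
          wd <- fit$windows_direct; wd$effect_type <- "direct"
          wm <- fit$windows_maternal; wm$effect_type <- "maternal"
          write_windows_tsv(rbind(wd, wm), file.path(outdir, "windows.tsv"))
          message("GWAS outputs written to ", outdir)
        }
      }
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("not found", conditionMessage(e))) 2L else 1L
  })
  invisible(as.integer(status))
}
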