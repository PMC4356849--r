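# End-to-end workflow: simulate or load -> genotype QC -> class enumeration
# -> final LCGA fit -> three-step covariate models -> cross-tabs and
# descriptives -> report bundle. All randomness flows from one master seed
# through stage-name-hashed sub-seeds, so adding a stage never perturbs
# earlier stages' streams.

#' Assemble a pipeline configuration
#'
#' Exactly one of `input` (paths to existing phenotype/genotype files) or
#' `sim_spec` (a [simulation_spec()]) must be supplied.
#'
#' @param input List with `phenotype_path`, optional `genotype_path`,
#'   `genotype_format`.
#' @param sim_spec A [simulation_spec()] for simulate-mode runs.
#' @param k_range Class counts to enumerate.
#' @param k_select Class count for the final fit; `NULL` uses the
#'   enumeration's selection flag (falling back to the best BIC).
#' @param n_starts Starts for the final fit.
#' @param lrt Run bootstrap LRTs during enumeration?
#' @param n_boot Bootstrap replicates per LRT.
#' @param snps SNP names to model; default all passing QC.
#' @param models Which covariate models to run.
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed.
#' @return A `run_config`.
#' @export
run_config <- function(input = NULL, sim_spec = NULL, k_range = 2:6,
                       k_select = NULL, n_starts = 20L, lrt = FALSE,
                       n_boot = 99L, snps = NULL,
                       models = c("main", "interaction"),
                       out_dir = tempfile("ptstraj_run_"), seed = 1L) {
  if (is.null(input) == is.null(sim_spec))
    stop("exactly one of `input` or `sim_spec` must be supplied",
         call. = FALSE)
  structure(list(input = input, sim_spec = sim_spec, k_range = k_range,
                 k_select = k_select, n_starts = n_starts, lrt = lrt,
                 n_boot = n_boot, snps = snps, models = models,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

write_tab <- function(df, dir, name) {
  path <- file.path(dir, name)
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_full(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  path
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full trajectory / gene-by-environment pipeline
#'
#' Emits a report bundle: fit-comparison table, trajectory summary,
#' regression results for every SNP x model x contrast, overall and
#' abuse-stratified genotype cross-tabs, QC report, per-subject posterior
#' export, a trajectory figure, and a manifest with versions, sub-seeds,
#' and a config hash. Outputs are deterministic given the master seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(simulate = derive_seed(config$seed, "simulate"),
                fit = derive_seed(config$seed, "fit"),
                select = derive_seed(config$seed, "select"),
                regress = derive_seed(config$seed, "regress"))

  cohort <- run_stage("data", {
    if (!is.null(config$sim_spec)) {
      spec <- config$sim_spec
      spec$seed <- seeds$simulate
      simulate_cohort(spec)
    } else {
      read_dataset(config$input$phenotype_path,
                   config$input$genotype_path,
                   config$input$genotype_format %||% "table")
    }
  })

  qc <- run_stage("qc", {
    snps_all <- attr(cohort, "snp_names")
    g <- as.matrix(as.data.frame(cohort)[, paste0("dosage_", snps_all),
                                         drop = FALSE])
    colnames(g) <- snps_all
    genotype_qc(g)
  })
  snps <- config$snps %||% qc$report$snp[qc$report$pass]

  enum <- run_stage("select", {
    enumerate_classes(cohort, k_range = config$k_range,
                      n_starts = config$n_starts, seed = seeds$select,
                      lrt = config$lrt, n_boot = config$n_boot)
  })
  k_final <- config$k_select %||% {
    sel <- enum$K[enum$selected]
    if (length(sel)) sel[1L] else enum$K[which.min(enum$bic)]
  }

  fit <- run_stage("fit", {
    fits <- attr(enum, "fits")
    fits[[as.character(k_final)]] %||%
      fit_lcga(cohort, k_final, n_starts = config$n_starts,
               seed = seeds$fit)
  })
  labels <- if (fit$params$K == 4L) label_trajectories(fit) else
    paste0("class", seq_len(fit$params$K))

  reg <- run_stage("regress", {
    out <- list()
    for (snp in snps) {
      if ("main" %in% config$models) {
        r <- run_main_effects_model(cohort, fit, snp)
        out[[paste0(snp, ":main")]] <- r
      }
      if ("interaction" %in% config$models) {
        r <- run_interaction_model(cohort, fit, snp)
        out[[paste0(snp, ":interaction")]] <- r
      }
    }
    out
  })
  reg_tab <- do.call(rbind, lapply(names(reg), function(nm) {
    r <- reg[[nm]]
    tab <- apply_bonferroni(r, n_snps = max(length(snps), 1L))
    cbind(snp = r$snp, model = r$model_tag, tab)
  }))
  if (is.null(reg_tab))
    reg_tab <- data.frame(snp = character(0), model = character(0),
                          contrast = character(0))

  desc <- run_stage("describe", {
    df <- as.data.frame(cohort)
    rows <- list(
      data.frame(variable = "pts_w1", value = mean(df$pts_w1),
                 sd = stats::sd(df$pts_w1), n = sum(!is.na(df$pts_w1))),
      data.frame(variable = "pts_w2", value = mean(df$pts_w2, na.rm = TRUE),
                 sd = stats::sd(df$pts_w2, na.rm = TRUE),
                 n = sum(!is.na(df$pts_w2))),
      data.frame(variable = "pts_w3", value = mean(df$pts_w3, na.rm = TRUE),
                 sd = stats::sd(df$pts_w3, na.rm = TRUE),
                 n = sum(!is.na(df$pts_w3))),
      data.frame(variable = "abuse", value = mean(df$cts_total),
                 sd = stats::sd(df$cts_total), n = nrow(df)),
      data.frame(variable = "age", value = mean(df$age),
                 sd = stats::sd(df$age), n = nrow(df)),
      data.frame(variable = "female", value = mean(df$female),
                 sd = NA_real_, n = nrow(df)))
    rge <- lapply(snps, function(snp) {
      r <- spearman_rge(df[[paste0("dosage_", snp)]], df$cts_total)
      data.frame(variable = paste0("rge_", snp), value = r$rho,
                 sd = NA_real_, n = r$n)
    })
    do.call(rbind, c(rows, rge))
  })

  crosstabs <- run_stage("crosstab", {
    df <- as.data.frame(cohort)
    modal_lab <- factor(labels[fit$modal_class], levels = labels)
    lapply(snps, function(snp) {
      dose <- df[[paste0("dosage_", snp)]]
      list(overall = crosstab_by_class(modal_lab, dose),
           stratified = crosstab_by_class(modal_lab, dose,
                                          stratifier = df$cts_total))
    }) |> stats::setNames(snps)
  })

  # ---- report bundle -------------------------------------------------
  dirp <- config$out_dir
  traj <- data.frame(class = labels,
                     proportion = fit$params$pi,
                     modal_n = tabulate(fit$modal_class, fit$params$K),
                     intercept = fit$params$beta[, 1L],
                     linear = fit$params$beta[, 2L],
                     quadratic = fit$params$beta[, 3L],
                     fitted_trajectories(fit))
  post <- assign_modal_class(fit, cohort$subject_id)
  post$label <- labels[post$modal_class]
  ct_rows <- do.call(rbind, lapply(names(crosstabs), function(snp) {
    do.call(rbind, lapply(c("overall", "stratified"), function(kind) {
      tabs <- crosstabs[[snp]][[kind]]$tables
      do.call(rbind, lapply(names(tabs), function(stratum) {
        cnt <- tabs[[stratum]]$counts
        pct <- tabs[[stratum]]$percent
        data.frame(snp = snp, table = kind, stratum = stratum,
                   class = rownames(cnt),
                   n0 = cnt[, 1L], n1 = cnt[, 2L], n2 = cnt[, 3L],
                   pct0 = pct[, 1L], pct1 = pct[, 2L], pct2 = pct[, 3L],
                   row.names = NULL)
      }))
    }))
  }))
  paths <- c(
    fit_comparison = write_tab(as.data.frame(enum), dirp,
                               "fit_comparison.tsv"),
    trajectories = write_tab(traj, dirp, "trajectories.tsv"),
    regression = write_tab(reg_tab, dirp, "regression_results.tsv"),
    crosstabs = write_tab(ct_rows, dirp, "crosstabs.tsv"),
    qc = write_tab(qc$report, dirp, "qc_report.tsv"),
    descriptives = write_tab(desc, dirp, "descriptives.tsv"),
    posteriors = write_tab(post, dirp, "posteriors.tsv"))
  fig <- tryCatch(
    render_trajectory_plot(fit, file.path(dirp, "trajectories.png"),
                           labels = labels),
    error = function(e) NA_character_)
  manifest <- list(package = "ptstraj",
                   version = as.character(utils::packageVersion("ptstraj")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   master_seed = config$seed,
                   stage_seeds = seeds,
                   k_selected = k_final,
                   n_subjects = fit$n,
                   snps = as.list(snps),
                   config_hash = config_hash(utils::capture.output(
                     utils::str(config[setdiff(names(config),
                                               "out_dir")]))))
  jsonlite::write_json(manifest, file.path(dirp, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, qc = qc, enumeration = enum, fit = fit,
                 labels = labels, regressions = reg,
                 regression_table = reg_tab, crosstabs = crosstabs,
                 paths = c(paths, manifest = file.path(dirp,
                                                       "manifest.json"),
                           figure = fig)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot estimated mean trajectories
#'
#' One fitted mean curve per class across the three waves, with the
#' probable-PTSD cut-off drawn as a horizontal reference line.
#'
#' @param fit An `lcga_fit`.
#' @param file Output path (`.png`, or `.pdf` fallback when no PNG device
#'   is available).
#' @param cutoff Cut-off line (default 44).
#' @param labels Class labels for the legend.
#' @return The path written, invisibly.
#' @export
render_trajectory_plot <- function(fit, file, cutoff = 44, labels = NULL) {
  mu <- fitted_trajectories(fit)
  K <- nrow(mu)
  if (is.null(labels)) labels <- rownames(mu)
  opened <- tryCatch({
    grDevices::png(file, width = 800, height = 600)
    TRUE
  }, error = function(e) FALSE)
  if (!opened) {
    file <- sub("\\.png$", ".pdf", file)
    grDevices::pdf(file, width = 8, height = 6)
  }
  on.exit(grDevices::dev.off())
  cols <- grDevices::hcl.colors(max(K, 2L), "Dark 2")
  graphics::matplot(1:3, t(mu), type = "b", pch = 19, lty = 1, lwd = 2,
                    col = cols, xaxt = "n", xlab = "Wave",
                    ylab = "Estimated PCL-C mean",
                    ylim = range(c(mu, cutoff)) + c(-5, 5))
  graphics::axis(1, at = 1:3, labels = paste0("W", 1:3))
  graphics::abline(h = cutoff, lty = 2, col = "grey40")
  graphics::legend("topright", legend = labels, col = cols[seq_len(K)],
                   lwd = 2, bty = "n")
  invisible(file)
}
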