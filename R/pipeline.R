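#' Run the full simulate-QC-fit-report pipeline
#'
#' Orchestrates the stages end to end from a single configuration:
#' simulation (or file input), phenotype/SNP/animal quality control,
#' relationship matrices, the weighted single-step association fit, window
#' selection and optional gene annotation. Every stage output is written
#' under `out_dir` and checksummed into a manifest, so a re-run with the
#' same configuration and seed reproduces the outputs byte for byte.
#'
#' @param config list with either `sim` (a [sim_config]) or `paths` (named
#'   list `genotypes`, `map`, `pedigree`, `phenotypes`), exactly one of the
#'   two; `model` (a [model_spec]); optional `qc` (a [qc_thresholds]),
#'   `genes` (gene coordinate table for annotation), and the fit settings
#'   `n_iterations`, `block_size`, `threshold`, `use_dgv`, `g_coef`,
#'   `a_coef`.
#' @param out_dir output directory, created if needed.
#' @param seed integer seed overriding `config$sim$seed`.
#' @return the manifest: list of stage outputs, parameters and md5 checksums.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  has_sim <- !is.null(config$sim); has_paths <- !is.null(config$paths)
  if (has_sim == has_paths)
    stop("provide exactly one of config$sim and config$paths")
  if (is.null(config$model)) stop("config$model (a model_spec) is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  outputs <- character(0)
  note <- function(stage, files) {
    stages <<- c(stages, stage)
    outputs <<- c(outputs, files)
  }

  if (has_sim) {
    sim <- config$sim
    if (!is.null(seed)) sim$seed <- as.integer(seed)
    ped <- simulate_pedigree(sim)
    panel <- simulate_genotypes(ped, sim)
    phenotypes <- simulate_phenotypes(ped, panel, sim)
    f <- file.path(out_dir, c("pedigree.csv", "genotypes.tsv", "map.tsv",
                              "phenotypes.tsv"))
    write_pedigree(ped, f[1])
    write_genotypes(panel, f[2], f[3])
    utils::write.table(phenotypes, f[4], sep = "\t", row.names = FALSE,
                       quote = FALSE)
    note("simulate", f)
  } else {
    ped <- read_pedigree(config$paths$pedigree)
    panel <- read_genotypes(config$paths$genotypes, config$paths$map)
    phenotypes <- utils::read.delim(config$paths$phenotypes,
                                    stringsAsFactors = FALSE)
    note("load", unlist(config$paths))
  }

  qc <- if (is.null(config$qc)) qc_thresholds() else config$qc
  fa <- filter_animals(panel, ped, phenotypes, qc)
  fs <- filter_snps(fa$panel, qc)
  panel <- fs$panel
  qf <- file.path(out_dir, "qc_report.tsv")
  qcdf <- rbind(
    data.frame(unit = "animals",
               filter = names(fa$report$removed_by_filter),
               removed = unlist(fa$report$removed_by_filter)),
    data.frame(unit = "SNPs", filter = names(fs$report$removed_by_filter),
               removed = unlist(fs$report$removed_by_filter)))
  utils::write.table(qcdf, qf, sep = "\t", row.names = FALSE, quote = FALSE)
  note("qc", qf)

  fit <- wssgwas(panel, ped, phenotypes, config$model,
                 n_iterations = config$n_iterations %||% 2L,
                 block_size = config$block_size %||% 20L,
                 use_dgv = config$use_dgv %||% TRUE,
                 threshold = config$threshold %||% 1.0,
                 g_coef = config$g_coef %||% 0.95,
                 a_coef = config$a_coef %||% 0.05)
  f_eff <- file.path(out_dir, "snp_effects.tsv")
  utils::write.table(fit$effects, f_eff, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  f_win <- file.path(out_dir, "windows.tsv")
  win <- fit$windows
  win$selected <- win$gv_percent >= fit$threshold
  attr(win, "index") <- NULL
  utils::write.table(win, f_win, sep = "\t", row.names = FALSE, quote = FALSE)
  f_gebv <- file.path(out_dir, "gebv.tsv")
  gdf <- data.frame(animal = names(fit$solution$gebv),
                    gebv = unname(fit$solution$gebv))
  gdf$dgv <- fit$dgv[gdf$animal]
  utils::write.table(gdf, f_gebv, sep = "\t", row.names = FALSE, quote = FALSE)
  note("relationships", character(0))
  note("solve", f_gebv)
  note("wssgwas", c(f_eff, f_win))

  f_man <- file.path(out_dir, "manhattan.tsv")
  mh <- manhattan_table(fit$windows)
  utils::write.table(mh, f_man, sep = "\t", row.names = FALSE, quote = FALSE)
  note("manhattan", f_man)

  if (!is.null(config$genes)) {
    sel <- select_windows(fit$windows, fit$threshold)
    sel$trait <- config$model$trait
    ann <- map_windows_to_genes(sel, config$genes)
    f_ann <- file.path(out_dir, "annotated_windows.tsv")
    utils::write.table(as.data.frame(ann), f_ann, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    note("annotate", f_ann)
  }

  manifest <- list(stages = stages, outputs = outputs,
                   checksums = tools::md5sum(outputs),
                   seed = if (has_sim) sim$seed else NA_integer_,
                   parameters = list(
                     trait = config$model$trait,
                     sigma_a2 = config$model$sigma_a2,
                     sigma_e2 = config$model$sigma_e2,
                     n_iterations = config$n_iterations %||% 2L,
                     block_size = config$block_size %||% 20L,
                     threshold = config$threshold %||% 1.0),
                   fit = fit)
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cumulative-position table for Manhattan-style window plots
#'
#' Adds a cumulative genome coordinate for each window midpoint: chromosomes
#' are laid end to end in map order, so the x coordinate increases strictly
#' across chromosome boundaries.
#'
#' @param windows window table from a fit (`chrom`, `start_bp`, `end_bp`,
#'   `gv_percent`).
#' @return `data.frame` with `window_id`, `chrom`, `mid_bp`, `cum_mid`,
#'   `gv_percent`.
#' @export
manhattan_table <- function(windows) {
  if (!nrow(windows)) {
    warning("empty window table")
    return(data.frame(window_id = integer(0), chrom = character(0),
                      mid_bp = numeric(0), cum_mid = numeric(0),
                      gv_percent = numeric(0)))
  }
  ord <- order(as_chrom_order(windows$chrom), windows$start_bp)
  w <- windows[ord, , drop = FALSE]
  chrom_len <- tapply(w$end_bp, w$chrom, max)
  chroms <- unique(w$chrom)
  offset <- stats::setNames(cumsum(c(0, chrom_len[chroms][-length(chroms)])),
                            chroms)
  mid <- (w$start_bp + w$end_bp) / 2
  data.frame(window_id = w$window_id, chrom = w$chrom, mid_bp = mid,
             cum_mid = mid + offset[w$chrom], gv_percent = w$gv_percent,
             row.names = NULL)
}

#' Write a Manhattan-style window plot to a file
#'
#' @param windows window table from a fit.
#' @param file output PNG path.
#' @param threshold horizontal reference line (percent), NULL to omit.
#' @return the plotted table, invisibly.
#' @export
export_manhattan <- function(windows, file, threshold = 1.0) {
  mh <- manhattan_table(windows)
  grDevices::png(file, width = 900, height = 350)
  on.exit(grDevices::dev.off())
  if (nrow(mh)) {
    cols <- c("grey30", "steelblue")[1 + (as_chrom_order(mh$chrom) %% 2)]
    graphics::plot(mh$cum_mid, mh$gv_percent, pch = 16, col = cols,
                   xlab = "cumulative genome position (bp)",
                   ylab = "% additive genetic variance")
    if (!is.null(threshold))
      graphics::abline(h = threshold, lty = 2, col = "red")
  } else {
    graphics::plot.new()
  }
  invisible(mh)
}
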