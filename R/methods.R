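#' @export
print.wssgwas <- function(x, ...) {
  cat("Weighted single-step GWAS fit\n")
  cat(sprintf("  trait: %s   markers: %d   genotyped animals: %d\n",
              x$trait, nrow(x$effects), length(x$genotyped_ids)))
  cat(sprintf("  iterations: %d   window size: %d SNPs   threshold: %.2f%%\n",
              x$n_iterations, x$block_size, x$threshold))
  cat(sprintf("  windows: %d total, %d selected (max GV%% = %.2f)\n",
              nrow(x$windows), nrow(x$selected),
              max(x$windows$gv_percent)))
  invisible(x)
}

#' @export
summary.wssgwas <- function(object, ...) {
  structure(list(fit = object), class = "summary.wssgwas")
}

#' @export
print.summary.wssgwas <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-iteration diagnostics:\n")
  it <- do.call(rbind, lapply(f$iterations, function(z)
    data.frame(iteration = z$iteration, trace_D = z$trace_D,
               top_window = z$top_window,
               max_gv_percent = z$max_gv_percent)))
  print(it, row.names = FALSE)
  if (nrow(f$selected)) {
    cat("\nSelected QTL windows (GV% >=", f$threshold, "):\n")
    print(utils::head(f$selected[, c("window_id", "chrom", "start_bp",
                                     "end_bp", "n_snps", "gv_percent")], 15),
          row.names = FALSE)
  } else cat("\nNo window reached the selection threshold.\n")
  invisible(x)
}

#' Extract per-SNP effects from a WssGWAS fit
#' @param object a `wssgwas` fit.
#' @param ... unused.
#' @return named numeric vector of back-solved SNP effects (final iteration).
#' @export
coef.wssgwas <- function(object, ...) {
  stats::setNames(object$effects$u_hat, object$effects$snp)
}

#' Manhattan-style plot of window variance shares
#'
#' Plots the percentage of additive genetic variance explained by each SNP
#' window against the window midpoint on a cumulative genome axis, with
#' alternating shading per chromosome and the selection threshold drawn.
#'
#' @param x a `wssgwas` fit.
#' @param ... passed to [graphics::plot].
#' @export
plot.wssgwas <- function(x, ...) {
  mh <- manhattan_table(x$windows)
  cols <- c("grey30", "steelblue")[1 + (as_chrom_order(mh$chrom) %% 2)]
  graphics::plot(mh$cum_mid, mh$gv_percent, pch = 16, col = cols,
                 xlab = "cumulative genome position (bp)",
                 ylab = "% additive genetic variance", ...)
  graphics::abline(h = x$threshold, lty = 2, col = "red")
  invisible(mh)
}

#' @export
print.ssgblup <- function(x, ...) {
  cat("Single-step GBLUP fit (trait:", x$trait, ")\n")
  cat(sprintf("  %d fixed-effect columns, %d breeding values, %d DGV\n",
              length(x$b_hat), length(x$gebv), length(x$dgv)))
  cat(sprintf("  lambda = %.4g, relative residual %.2e\n", x$lambda,
              x$convergence$relative_residual))
  invisible(x)
}
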