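# S3 methods for the fitted model object.

#' @export
print.methaplo_fit <- function(x, ...) {
  kept <- if (is.null(x$kept)) NA_integer_ else sum(x$kept)
  cat(sprintf(
    "<methaplo_fit> %s mode: %d reads in %d chain(s)%s on %s:%d-%d\n",
    x$config$mode, length(x$reads$units), length(x$chains),
    if (is.na(kept)) "" else sprintf(" (%d kept)", kept),
    x$window$chrom, x$window$start, x$window$end
  ))
  cat(sprintf(
    "  log posterior %.2f after %d pass(es)%s\n",
    x$logLik, x$passes,
    if (x$converged) "" else " [pass limit reached]"
  ))
  invisible(x)
}

#' @export
summary.methaplo_fit <- function(object, ...) {
  structure(
    list(
      fit = object,
      chains = chains(object),
      n_moves = length(object$trajectory) - 1L
    ),
    class = "summary.methaplo_fit"
  )
}

#' @export
print.summary.methaplo_fit <- function(x, n_show = 10L, ...) {
  print(x$fit)
  cat(sprintf("  %d accepted move(s)\n\nChains:\n", x$n_moves))
  df <- x$chains[, c(
    "chain", "start", "end", "length", "n_reads",
    "depth_fraction", "mean_methylation", "kept"
  )]
  df$depth_fraction <- round(df$depth_fraction, 3)
  df$mean_methylation <- round(df$mean_methylation, 3)
  # kept chains first, then the largest of the rest
  o <- order(-df$kept, -df$n_reads, df$start)
  shown <- df[o[seq_len(min(n_show, nrow(df)))], ]
  shown <- shown[order(shown$start), ]
  print(shown, row.names = FALSE)
  if (nrow(df) > n_show) {
    hidden <- df[o[-seq_len(n_show)], ]
    cat(sprintf(
      "  ... and %d more chain(s) (%d read(s) in total, all %s)\n",
      nrow(hidden), sum(hidden$n_reads),
      if (any(hidden$kept)) "minor" else "filtered out"
    ))
  }
  invisible(x)
}

#' @export
logLik.methaplo_fit <- function(object, ...) {
  structure(object$logLik,
    df = NA_integer_, nobs = length(object$reads$units),
    class = "logLik"
  )
}

#' Plot a fitted haplotype-chain model
#'
#' Draws each read as a horizontal segment, grouped and colored by chain,
#' with the chain's inferred CpG methylation shown as filled (methylated)
#' or open (unmethylated) circles on the chain midline.
#'
#' @param x A `methaplo_fit`.
#' @param kept_only Show only chains kept by [filter_chains()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.methaplo_fit <- function(x, kept_only = FALSE, ...) {
  kept <- if (is.null(x$kept)) rep(TRUE, length(x$chains)) else x$kept
  chs <- x$chains[if (kept_only) which(kept) else seq_along(x$chains)]
  if (!length(chs)) {
    graphics::plot.new()
    return(invisible(x))
  }
  y <- 0
  cols <- grDevices::hcl.colors(max(2L, length(chs)), "Dark 3")
  graphics::plot(
    NA,
    xlim = c(x$window$start, x$window$end),
    ylim = c(0, sum(vapply(chs, function(c) c$n_reads, integer(1L))) + 2 * length(chs)),
    xlab = sprintf("position on %s", x$window$chrom), ylab = "",
    yaxt = "n", ...
  )
  for (k in seq_along(chs)) {
    ch <- chs[[k]]
    mid <- y + ch$n_reads / 2 + 1
    for (m in ch$members) {
      y <- y + 1
      u <- x$reads$units[[m]]
      for (s in seq_len(nrow(u$segs))) {
        graphics::segments(u$segs[s, 1L], y, u$segs[s, 2L], y, col = cols[k])
      }
    }
    cpg <- which(ch$g %in% c("C", "M") &
      bitwAnd(
        x$window$context[(ch$start:ch$end) - x$window$start + 1L],
        .CTX[["CPG_C"]]
      ) > 0L)
    if (length(cpg)) {
      graphics::points(ch$start + cpg - 1L, rep(mid, length(cpg)),
        pch = 21, cex = 0.8,
        bg = ifelse(ch$g[cpg] == "M", "black", "white")
      )
    }
    y <- y + 2
  }
  invisible(x)
}
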