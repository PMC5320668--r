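# Model configuration with per-mode defaults.

.MODES <- c("wgbs-single", "wgbs-paired", "nome")

#' Model configuration
#'
#' Collects the tunable parameters of the haplotype-chain model with
#' per-mode defaults.  The feasibility constants control when a read may
#' join a chain: the overlap between chain and read must span at least `K0`
#' base pairs and contain at least `K1` CpGs, `K2` isolated CpGs, and `K3`
#' isolated GpCs.  Defaults: WGBS single `K0=40, K1=1`; WGBS paired
#' `K0=50, K1=2` (paired reads are longer, so more overlap can be
#' required); NOMe `K0=40, K1=0, K3=2` (clustering evidence comes from
#' enzymatic GpC methylation).  The noise filter keeps a chain when
#' `a <= chain length + b * depth fraction`; defaults `a=5000, b=20000`
#' for single-layout WGBS and `a=10000, b=28500` otherwise (the paired
#' WGBS values, reused for NOMe which is paired here).
#'
#' @param mode One of `"wgbs-paired"` (default), `"wgbs-single"`, `"nome"`.
#' @param conversion_rate Bisulfite conversion success rate (default 0.95);
#'   the model's failed-conversion rate is `1 - conversion_rate`.
#' @param beta Inappropriate-conversion rate (default 0.05).
#' @param K0,K1,K2,K3 Feasibility constants; `NULL` takes the mode default.
#' @param q Prior confidence weight in (0,1) for the reference/known-variant
#'   genotype prior (default 0.9999); `q = 0.5` disables reference guidance.
#' @param filter_a,filter_b Noise-filter constants in bp; `NULL` takes the
#'   mode default.
#' @param use_db Whether known variants extend the genotype prior support
#'   (default `TRUE`; without a variant set only the reference base is
#'   supported, private mutations aside).
#' @param max_passes Coordinate-ascent pass limit (default 50).
#' @return An object of class `methaplo_config`.
#' @export
#' @examples
#' methaplo_config("nome")
methaplo_config <- function(mode = c("wgbs-paired", "wgbs-single", "nome"),
                            conversion_rate = 0.95, beta = 0.05,
                            K0 = NULL, K1 = NULL, K2 = NULL, K3 = NULL,
                            q = 0.9999,
                            filter_a = NULL, filter_b = NULL,
                            use_db = TRUE, max_passes = 50L) {
  mode <- match.arg(mode)
  defs <- switch(mode,
    "wgbs-single" = list(K0 = 40L, K1 = 1L, K2 = 0L, K3 = 0L, a = 5000, b = 20000),
    "wgbs-paired" = list(K0 = 50L, K1 = 2L, K2 = 0L, K3 = 0L, a = 10000, b = 28500),
    "nome"        = list(K0 = 40L, K1 = 0L, K2 = 0L, K3 = 2L, a = 10000, b = 28500)
  )
  if (is.null(K0)) K0 <- defs$K0
  if (is.null(K1)) K1 <- defs$K1
  if (is.null(K2)) K2 <- defs$K2
  if (is.null(K3)) K3 <- defs$K3
  if (is.null(filter_a)) filter_a <- defs$a
  if (is.null(filter_b)) filter_b <- defs$b
  stopifnot(
    K0 >= 0, K1 >= 0, K2 >= 0, K3 >= 0,
    q > 0, q < 1, filter_a >= 0, filter_b >= 0, max_passes >= 1
  )
  structure(
    list(
      mode = mode,
      params = conversion_params(conversion_rate, beta),
      K0 = as.integer(K0), K1 = as.integer(K1),
      K2 = as.integer(K2), K3 = as.integer(K3),
      q = q, filter_a = filter_a, filter_b = filter_b,
      use_db = isTRUE(use_db), max_passes = as.integer(max_passes)
    ),
    class = "methaplo_config"
  )
}

#' @export
print.methaplo_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<methaplo_config> mode=%s\n",
      "  conversion_rate=%g (failed-conversion rate %g), beta=%g\n",
      "  feasibility K0=%d bp, K1=%d CpG, K2=%d isolated CpG, K3=%d isolated GpC\n",
      "  prior q=%g (use_db=%s); filter a=%g, b=%g; max_passes=%d\n"
    ),
    x$mode, x$params$conversion_rate, x$params$alpha_fail, x$params$beta,
    x$K0, x$K1, x$K2, x$K3, x$q, x$use_db, x$filter_a, x$filter_b, x$max_passes
  ))
  invisible(x)
}

#' Read a configuration from a YAML file
#'
#' The file may contain any argument of [methaplo_config()] plus the
#' pipeline fields used by [run_pipeline()] (`alignments`, `reference`,
#' `region`, `variants`, `out_prefix`).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `config` (a `methaplo_config`) and `io`
#'   (the pipeline fields).
#' @export
read_config_file <- function(path) {
  y <- yaml::read_yaml(path)
  cfg_args <- intersect(names(y), names(formals(methaplo_config)))
  io_keys <- c("alignments", "reference", "region", "variants", "out_prefix")
  list(
    config = do.call(methaplo_config, y[cfg_args]),
    io = y[intersect(names(y), io_keys)]
  )
}
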