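# Run manifests: enough metadata to reproduce any result table -
# bit-for-bit for deterministic stages, statistically for stochastic ones.

#' Build a run manifest
#'
#' @param params The \code{xb_params} used.
#' @param protocol Protocol descriptor (list or character).
#' @param seed Seed(s) used for the run.
#' @param ... Further descriptor fields (problem sizes, series, ...).
#' @return A list of class \code{xb_manifest}.
#' @export
run_manifest <- function(params, protocol = NULL, seed = NULL, ...) {
  structure(list(
    param_hash = param_hash(params),
    hypothesis = attr(params, "hypothesis") %||% "none",
    temperature_regime = params$temperature_regime,
    seed = seed,
    protocol = protocol,
    package_version = as.character(utils::packageVersion("crossbridge")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    ...
  ), class = "xb_manifest")
}

#' @rdname run_manifest
#' @param manifest An \code{xb_manifest}.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @export
print.xb_manifest <- function(x, ...) {
  cat("<xb_manifest> params", x$param_hash, "hypothesis", x$hypothesis,
      "seed", deparse(x$seed), "\n")
  invisible(x)
}
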