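#' Pipeline configuration
#'
#' Collects every tunable parameter of the atrophy pipeline. The defaults are
#' the fixed parameter set used for all experiments: gBSI region variant,
#' single intensity window, differential bias correction on with kernel
#' radius 5, k-means mask dilations 3, binary-XOR dilate/erode 1/1, pBSI
#' thresholds eta 0.95 / zeta 0.90 with 0 erosions / 1 dilation,
#' binarization threshold 0.5, 6-connected morphology.
#'
#' @param variant boundary region variant: `"gbsi"`, `"kn"` (binary XOR),
#'   `"pbsi1"` or `"pbsig"`.
#' @param window_mode `"single"` (CSF-GM border) or `"double"` (CSF-GM plus
#'   GM-WM, for structures such as the hippocampus).
#' @param dbc logical, apply differential bias correction.
#' @param dbc_kernel_radius DBC median-filter half-width, voxels.
#' @param kmeans_dilations dilations of the binarized mask before k-means.
#' @param xor_dilate,xor_erode morphology counts for the binary XOR region.
#' @param pbsi_eta,pbsi_zeta,pbsi_ne,pbsi_nd,pbsi_gamma fuzzy-region
#'   parameters (see [pbsi_params()]).
#' @param binarize_threshold probability cut for all binarizations.
#' @param connectivity 6 or 26, structuring element for all morphology.
#' @param kappa_override optional fixed gBSI gain factor (normally adaptive).
#' @param seed integer seed recorded in reports (the deterministic pipeline
#'   itself draws no random numbers).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(variant = c("gbsi", "kn", "pbsi1", "pbsig"),
                            window_mode = c("single", "double"),
                            dbc = TRUE, dbc_kernel_radius = 5L,
                            kmeans_dilations = 3L,
                            xor_dilate = 1L, xor_erode = 1L,
                            pbsi_eta = 0.95, pbsi_zeta = 0.90,
                            pbsi_ne = 0L, pbsi_nd = 1L, pbsi_gamma = 1,
                            binarize_threshold = 0.5,
                            connectivity = 6L,
                            kappa_override = NULL,
                            seed = 1L) {
  variant <- match.arg(variant)
  window_mode <- match.arg(window_mode)
  stopifnot(dbc_kernel_radius >= 1, kmeans_dilations >= 0,
            xor_dilate >= 0, xor_erode >= 0,
            binarize_threshold > 0, binarize_threshold < 1,
            connectivity %in% c(6L, 26L))
  structure(list(
    variant = variant, window_mode = window_mode,
    dbc = isTRUE(dbc), dbc_kernel_radius = as.integer(dbc_kernel_radius),
    kmeans_dilations = as.integer(kmeans_dilations),
    xor_dilate = as.integer(xor_dilate), xor_erode = as.integer(xor_erode),
    pbsi_eta = pbsi_eta, pbsi_zeta = pbsi_zeta,
    pbsi_ne = as.integer(pbsi_ne), pbsi_nd = as.integer(pbsi_nd),
    pbsi_gamma = pbsi_gamma,
    binarize_threshold = binarize_threshold,
    connectivity = as.integer(connectivity),
    kappa_override = kappa_override,
    seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Write a configuration to a flat key-value file
#'
#' One `key = value` pair per line (a minimal TOML-like dialect); strings
#' unquoted, logicals as `true`/`false`, unset optional keys omitted.
#'
#' @param config a [pipeline_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "true" else "false")
    as.character(v)
  }
  keep <- !vapply(config, is.null, logical(1))
  lines <- paste(names(config)[keep], "=",
                 vapply(config[keep], fmt, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration from a flat key-value file
#'
#' @param path file written by [write_config()] (or by hand in the same
#'   dialect; `#` starts a comment).
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$",
                                  lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad))
    stop("parse error in config line ", bad[1], ": '", lines[bad[1]], "'")
  vals <- lapply(kv, function(m) {
    v <- trimws(m[3])
    if (v %in% c("true", "false")) return(v == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  })
  names(vals) <- vapply(kv, `[`, character(1), 2)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat("  ", nm, " = ", if (is.null(v)) "(adaptive)" else as.character(v),
        "\n", sep = "")
  }
  invisible(x)
}
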