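#' Derive a per-module seed from a global run seed
#'
#' One global seed fans out deterministically to the stochastic stages of
#' a run, so changing how one stage consumes random numbers cannot
#' perturb another. The derivation is a fixed integer hash of the label,
#' mixed with the seed modulo a Mersenne prime; results stay within the
#' 32-bit range R accepts in [set.seed()].
#'
#' @param seed Integer global seed.
#' @param label Character label of the consuming stage.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, length(label) == 1L)
  h <- 2166136261
  for (ch in utf8ToInt(label)) {
    h <- (bitwXor(as.integer(h %% 2147483647), ch) * 16777619) %% 2147483647
  }
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# FNV-1a style hash of a deparsed R object; used to stamp run manifests
# and output headers so a result can be traced to its configuration.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- (bitwXor(as.integer(h %% 2147483647), ch) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Write and read tab-separated tables with provenance headers
#'
#' All tabular interchange in the package is plain TSV (header row,
#' UTF-8, '.' decimal). `write_tsv()` can prepend `#`-prefixed comment
#' lines carrying the seed and config hash of the producing run;
#' `read_tsv()` skips them.
#'
#' @param x Data frame.
#' @param path File path.
#' @param comments Character vector of comment lines (without the leading
#'   `#`), or `NULL`.
#' @export
write_tsv <- function(x, path, comments = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file of parameter blocks.
#' @return Named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write a run manifest
#'
#' Records the seed, configuration hash and input checksums of a run as
#' JSON next to its outputs.
#'
#' @param path Output path for the JSON manifest.
#' @param seed Integer seed of the run.
#' @param config Configuration object (hashed into the manifest).
#' @param inputs Named character vector of input file paths, hashed by
#'   content; optional.
#' @export
write_run_manifest <- function(path, seed, config, inputs = NULL) {
  m <- list(
    package = "riboneutral",
    version = as.character(utils::packageVersion("riboneutral")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = config_hash(config))
  if (!is.null(inputs)) {
    m$inputs <- lapply(inputs, function(p) {
      list(path = p,
           hash = config_hash(readLines(p, warn = FALSE)))
    })
  }
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Landscape table I/O
#'
#' A landscape maps genotypes to relative activity (RA). On disk it is a
#' TSV with columns `sequence`, `ra` and, for combinatorially complete
#' biallelic landscapes, the 0-based binary `index` (locus 1 = least
#' significant bit).
#'
#' @param landscape Data frame with at least columns `sequence` and `ra`.
#' @param path File path.
#' @param comments Optional comment lines, see [write_tsv()].
#' @export
write_landscape_tsv <- function(landscape, path, comments = NULL) {
  stopifnot(all(c("sequence", "ra") %in% names(landscape)))
  write_tsv(landscape, path, comments)
}

#' @rdname write_landscape_tsv
#' @export
read_landscape_tsv <- function(path) {
  x <- read_tsv(path)
  stopifnot(all(c("sequence", "ra") %in% names(x)))
  x
}
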