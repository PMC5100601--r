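#' Load a YAML run configuration
#'
#' Validates a structured-text configuration against the known keys, applies
#' the documented defaults (gamma = 35/s, beta = gamma, footprint = 9,
#' depletion factor = 0.25, alpha = 0.3/s), and rejects unknown or
#' mistyped keys by name.
#'
#' @param path path to a YAML file.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- list(
    transcriptome = NULL, trna_table = NULL, alpha_table = NULL,
    out_dir = ".", seed = 1L, threshold = 0.5, factor = 0.25,
    depletion_trna = NULL, gamma = 35, beta = NULL, footprint = 9L,
    alpha = 0.3, alpha_grid = c(0.3, 0.2, 0.1, 0.05, 0.02, 0.01),
    target_terminations = 1000, max_time = 1e5, window = c(1L, 30L),
    scaling = NULL)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  num_keys <- c("seed", "threshold", "factor", "gamma", "footprint", "alpha",
                "target_terminations", "max_time")
  for (key in num_keys) {
    if (!is.null(cfg[[key]]) &&
        (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1))
      abort(sprintf("config key `%s` must be a single number", key))
  }
  if (is.null(cfg$beta)) cfg$beta <- cfg$gamma
  for (key in c("transcriptome", "trna_table", "alpha_table")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      abort(sprintf("config key `%s`: no such file: %s", key, cfg[[key]]))
  }
  structure(cfg, class = "run_config")
}

# stable content hash (rolling polynomial over the deparsed object),
# for output headers
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 1000000007
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Write / read a self-describing result table
#'
#' TSV with `#`-prefixed metadata header lines (tool version, master seed,
#' config hash). Numeric columns are written with 17 significant digits so
#' the file round-trips losslessly; byte-identical inputs produce
#' byte-identical files.
#'
#' @param x a data frame of results.
#' @param path output path.
#' @param seed master seed to record.
#' @param config optional configuration object to hash into the header.
#' @return `path` invisibly ([write_run_table()]); a tibble
#'   ([read_run_table()]).
#' @export
write_run_table <- function(x, path, seed = NA, config = NULL) {
  header <- c(
    sprintf("# codonqueue %s", as.character(packageVersion("codonqueue"))),
    sprintf("# seed: %s", as.character(seed)),
    sprintf("# config: %s", if (is.null(config)) "none" else config_hash(config)))
  x <- as_tibble(x)
  for (cl in names(x)) {
    if (is.double(x[[cl]])) x[[cl]] <- sprintf("%.17g", x[[cl]])
    if (is.list(x[[cl]])) x[[cl]] <- NULL  # list-columns are not serialised
  }
  lines <- c(header, paste(names(x), collapse = "\t"))
  if (nrow(x) > 0) {
    body <- do.call(paste, c(unname(as.list(x)), sep = "\t"))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_table
#' @export
read_run_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
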