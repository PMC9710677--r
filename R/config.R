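#' Parse an INI-style configuration
#'
#' The run is driven by a single plain-text configuration file in the
#' Windows INI style. Three sections are recognised:
#'
#' \describe{
#'   \item{`[PARAMS]`}{`motif`, `stage1_repeats`, `stage2_min_repeats`,
#'     `wildcard_prefix`, `strands` (`both`/`forward`/`reverse`), `mode`
#'     (`regions`/`full`), `workers`, `scale` (normalisation constant,
#'     default 1e6 = telomeric reads per million records).}
#'   \item{`[FILTER]`}{`exclude_duplicates`, `exclude_secondary`,
#'     `exclude_supplementary`, `exclude_qcfail` (booleans, all default
#'     true), `min_read_length` (default 0).}
#'   \item{`[INCLUDES]`}{One region per line: `label` and `chrom:start-end`
#'     separated by whitespace, 1-based inclusive coordinates.}
#' }
#'
#' Keys are case-insensitive; `#` starts a comment. Every tunable is
#' resolved to an explicit value (defaults applied) so the returned object
#' can be echoed verbatim into reports for provenance. Unknown keys are an
#' error with `strict = TRUE`, otherwise a warning.
#'
#' @param text Configuration content: a single string or character vector of
#'   lines.
#' @param strict Logical; promote unknown-key warnings to errors.
#' @return An object of class `run_config`: a list with all `[PARAMS]` and
#'   `[FILTER]` values made explicit, the `includes` table (label, region
#'   string, line number), plus the derived `motif_spec` and, when any
#'   includes are present, the sorted `regions` [region_set()].
#' @examples
#' cfg <- parse_config(c("[PARAMS]", "motif = TTAGGG", "[INCLUDES]",
#'                       "chr1_tel  chr1:1-10000"))
#' cfg$stage1_repeats
#' @export
parse_config <- function(text, strict = FALSE) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  if (!length(text) || !any(nzchar(trimws(text)))) {
    stop("configuration error: empty configuration", call. = FALSE)
  }
  ini <- .parse_ini(text)

  defaults <- list(
    motif = "TTAGGG", stage1_repeats = 3L, stage2_min_repeats = 2L,
    wildcard_prefix = 3L, strands = "both", mode = "regions",
    workers = 1L, scale = 1e6)
  fdefaults <- list(
    exclude_duplicates = TRUE, exclude_secondary = TRUE,
    exclude_supplementary = TRUE, exclude_qcfail = TRUE,
    min_read_length = 0L)

  complain <- function(msg) {
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  params <- ini$sections[["params"]] %||% list()
  filter <- ini$sections[["filter"]] %||% list()
  for (k in setdiff(names(params), names(defaults))) {
    complain(sprintf("configuration: unknown key '%s' in [PARAMS]", k))
  }
  for (k in setdiff(names(filter), names(fdefaults))) {
    complain(sprintf("configuration: unknown key '%s' in [FILTER]", k))
  }
  for (s in setdiff(names(ini$sections), c("params", "filter", "includes"))) {
    complain(sprintf("configuration: unknown section [%s]", toupper(s)))
  }

  get_par <- function(src, defs, key) {
    v <- src[[key]]
    if (is.null(v)) return(defs[[key]])
    d <- defs[[key]]
    if (is.logical(d)) .parse_bool(v, key)
    else if (is.integer(d)) .check_count(suppressWarnings(as.numeric(v)), key,
                                         min = if (key %in% c("wildcard_prefix",
                                                              "min_read_length")) 0L else 1L)
    else if (is.numeric(d)) {
      x <- suppressWarnings(as.numeric(v))
      if (is.na(x) || x <= 0) {
        stop(sprintf("configuration error: %s must be a positive number", key),
             call. = FALSE)
      }
      x
    } else tolower(trimws(v))
  }

  cfg <- list()
  for (k in names(defaults)) cfg[[k]] <- get_par(params, defaults, k)
  cfg$motif <- toupper(if (is.null(params$motif)) defaults$motif else trimws(params$motif))
  if (!cfg$strands %in% c("both", "forward", "reverse")) {
    stop(sprintf("configuration error: strands must be both/forward/reverse, got '%s'",
                 cfg$strands), call. = FALSE)
  }
  if (!cfg$mode %in% c("regions", "full")) {
    stop(sprintf("configuration error: mode must be 'regions' or 'full', got '%s'",
                 cfg$mode), call. = FALSE)
  }
  for (k in names(fdefaults)) cfg[[k]] <- get_par(filter, fdefaults, k)

  cfg$includes <- ini$includes
  cfg$motif_spec <- build_motif_spec(cfg$motif, cfg$stage1_repeats,
                                     cfg$stage2_min_repeats,
                                     cfg$wildcard_prefix, cfg$strands)
  class(cfg) <- "run_config"
  if (nrow(cfg$includes) > 0L) {
    cfg$regions <- load_regions(cfg)
  } else if (cfg$mode == "regions") {
    stop("configuration error: no regions defined in [INCLUDES] but mode=regions",
         call. = FALSE)
  }
  cfg
}

#' Read and parse a configuration file
#'
#' @param path Path to an INI-style configuration file.
#' @inheritParams parse_config
#' @return A `run_config`; see [parse_config()].
#' @export
read_config <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("input error: configuration file '%s' not found", path),
         call. = FALSE)
  }
  parse_config(readLines(path, warn = FALSE), strict = strict)
}

# minimal INI reader: sections in [brackets], '#' comments, key = value
# pairs lower-cased; [INCLUDES] lines kept verbatim as label/region entries
# with their 1-based line numbers for error reporting.
.parse_ini <- function(lines) {
  sections <- list()
  includes <- data.frame(label = character(0), region = character(0),
                         line = integer(0), stringsAsFactors = FALSE)
  current <- NA_character_
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      current <- tolower(gsub("^\\[|\\]$", "", ln))
      if (!current %in% names(sections) && current != "includes") {
        sections[[current]] <- list()
      }
      next
    }
    if (is.na(current)) {
      stop(sprintf("configuration error at line %d: entry before any [SECTION]",
                   i), call. = FALSE)
    }
    if (current == "includes") {
      parts <- strsplit(ln, "[ \t]+")[[1]]
      if (length(parts) != 2L) {
        stop(sprintf(
          "configuration error at line %d: expected 'label chrom:start-end', got '%s'",
          i, ln), call. = FALSE)
      }
      includes <- rbind(includes, data.frame(
        label = parts[1L], region = parts[2L], line = i,
        stringsAsFactors = FALSE))
    } else {
      kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
      if (length(kv) != 3L) {
        stop(sprintf("configuration error at line %d: expected key = value, got '%s'",
                     i, ln), call. = FALSE)
      }
      sections[[current]][[tolower(trimws(kv[2L]))]] <- trimws(kv[3L])
    }
  }
  list(sections = sections, includes = includes)
}

.parse_bool <- function(v, key) {
  v <- tolower(trimws(v))
  if (v %in% c("true", "yes", "1", "on")) return(TRUE)
  if (v %in% c("false", "no", "0", "off")) return(FALSE)
  stop(sprintf("configuration error: %s must be a boolean, got '%s'", key, v),
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_config <- function(x, ...) {
  cat("telomotif run configuration\n")
  cat(sprintf("  motif=%s stage1_repeats=%d stage2_min_repeats=%d wildcard_prefix=%d strands=%s\n",
              x$motif, x$stage1_repeats, x$stage2_min_repeats,
              x$wildcard_prefix, x$strands))
  cat(sprintf("  mode=%s workers=%d scale=%g\n", x$mode, x$workers, x$scale))
  cat(sprintf("  filter: dup=%s sec=%s supp=%s qcfail=%s min_len=%d\n",
              x$exclude_duplicates, x$exclude_secondary,
              x$exclude_supplementary, x$exclude_qcfail, x$min_read_length))
  cat(sprintf("  includes: %d region(s)\n", nrow(x$includes)))
  invisible(x)
}
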