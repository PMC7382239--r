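#' Read a run configuration file
#'
#' Parses the declarative TOML-dialect configuration used by the experiment
#' runner and the command-line tools.  The supported subset covers what the
#' package writes: `[section]` and `[section.sub]` tables, `key = value`
#' pairs with string, number, boolean and flat-array values, and `#`
#' comments.  Keys mirror the [simulation_params()] and
#' [confinement_domain()] field names:
#'
#' ```
#' [domain]
#' kind = "box"
#' dimensions = [40.0, 15.0, 15.0]
#'
#' [params]
#' p_cross = 0.005
#' t_steps = 2000
#' ```
#'
#' @param path file path.
#' @return a nested named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- character(0)
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[[^]]+\\]$", ln)) {
      section <- strsplit(gsub("^\\[|\\]$", "", ln), ".", fixed = TRUE)[[1]]
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- parse_toml_value(trimws(substr(ln, eq + 1, nchar(ln))))
    out <- assign_path(out, c(section, key), val)
  }
  out
}

assign_path <- function(lst, path, val) {
  if (length(path) == 1) {
    lst[[path]] <- val
    return(lst)
  }
  sub <- lst[[path[1]]]
  if (is.null(sub)) sub <- list()
  lst[[path[1]]] <- assign_path(sub, path[-1], val)
  lst
}

parse_toml_value <- function(s) {
  if (grepl("^\\[.*\\]$", s)) {
    inner <- trimws(gsub("^\\[|\\]$", "", s))
    if (inner == "") return(list())
    parts <- trimws(strsplit(inner, ",")[[1]])
    vals <- lapply(parts, parse_toml_value)
    return(unlist(vals, use.names = FALSE))
  }
  if (grepl('^".*"$', s)) return(gsub('^"|"$', "", s))
  if (s %in% c("true", "false")) return(s == "true")
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  stop("cannot parse config value: ", s)
}

#' Write a run configuration file
#'
#' Inverse of [read_config()] for the supported subset; nested lists become
#' `[section]` tables.  Round-trips through [read_config()].
#'
#' @param config nested named list of scalars/flat vectors.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  fmt_val <- function(v) {
    one <- function(x) {
      if (is.character(x)) sprintf('"%s"', x)
      else if (is.logical(x)) tolower(as.character(x))
      else if (is.numeric(x) && x == round(x) && abs(x) < 2^31)
        sprintf("%d", as.integer(x))
      else sprintf("%.17g", x)
    }
    if (length(v) > 1) sprintf("[%s]", paste(vapply(v, one, character(1)),
                                             collapse = ", "))
    else one(v)
  }
  emit <- function(x, prefix) {
    scalars <- names(x)[!vapply(x, function(v) is.list(v) && !is.null(names(v)),
                                logical(1))]
    tables <- setdiff(names(x), scalars)
    out <- character(0)
    if (length(prefix))
      out <- c(out, sprintf("[%s]", paste(prefix, collapse = ".")))
    for (nm in scalars)
      out <- c(out, sprintf("%s = %s", nm, fmt_val(x[[nm]])))
    if (length(scalars) || length(prefix)) out <- c(out, "")
    for (nm in tables)
      out <- c(out, emit(x[[nm]], c(prefix, nm)))
    out
  }
  writeLines(emit(config, character(0)), path)
  invisible(path)
}

#' Build a domain and parameters from a configuration list
#'
#' @param config a list as returned by [read_config()], with `domain` and
#'   (optionally) `params` tables.
#' @return list with `domain` (a [confinement_domain()]) and `params`
#'   (a [simulation_params()]).
#' @export
config_to_run <- function(config) {
  if (is.null(config$domain)) stop("config has no [domain] table")
  domain <- confinement_domain(config$domain$kind, config$domain$dimensions)
  pl <- config$params
  if (is.null(pl)) pl <- list()
  known <- names(formals(simulation_params))
  pl <- pl[intersect(names(pl), known)]
  params <- do.call(simulation_params, pl)
  list(domain = domain, params = params)
}

#' Serialize a run setup to a configuration list
#' @param domain a [confinement_domain()].
#' @param params a [simulation_params()].
#' @return a nested list suitable for [write_config()].
#' @export
run_to_config <- function(domain, params) {
  list(domain = list(kind = domain$kind,
                     dimensions = as.numeric(domain$dimensions)),
       params = unclass(params))
}
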