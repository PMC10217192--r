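# Delimited-text writers/readers with a JSON metadata header. Every file the
# package writes round-trips through the matching reader, restoring both the
# data and the configuration needed to reproduce it.

meta_header <- function(kind, config) {
  cfg <- config
  if (is_landau_model(cfg$model)) {
    cfg$model <- cfg$model[c("alpha", "beta", "gamma", "name")]
  }
  c(
    sprintf("# landaucell %s v1", kind),
    paste0("# config: ",
           jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                            null = "null"))
  )
}

parse_meta <- function(path) {
  lines <- readLines(path, n = 2)
  if (!grepl("^# landaucell ", lines[1])) {
    rlang::abort(sprintf("'%s' is not a landaucell data file", path))
  }
  kind <- sub("^# landaucell (\\w+) v1.*$", "\\1", lines[1])
  cfg <- jsonlite::fromJSON(sub("^# config: ", "", lines[2]))
  if (!is.null(cfg$model)) {
    cfg$model <- new_landau_model(cfg$model$alpha, cfg$model$beta,
                                  cfg$model$gamma, cfg$model$name)
  }
  list(kind = kind, config = cfg)
}

write_table_with_meta <- function(df, path, kind, config) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta_header(kind, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_with_meta <- function(path) {
  meta <- parse_meta(path)
  df <- tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                            sep = "\t"))
  list(meta = meta, data = df)
}

#' Write / read a trajectory or ensemble as delimited text
#'
#' Tab-separated records (`t`, `m`, `xi`, plus `traj` for ensembles) preceded
#' by a JSON metadata header carrying the full simulation configuration, so a
#' file is sufficient to re-run the simulation that produced it.
#'
#' @param x A `landau_trajectory` or `landau_ensemble`.
#' @param path Output file.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns the restored object with its class and `config` attribute.
#' @export
write_trajectory <- function(x, path) {
  kind <- if (inherits(x, "landau_ensemble")) "ensemble" else if (inherits(x, "landau_trajectory")) "trajectory" else
    rlang::abort("`x` must be a landau_trajectory or landau_ensemble")
  write_table_with_meta(tibble::as_tibble(x), path, kind, attr(x, "config"))
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  r <- read_table_with_meta(path)
  out <- r$data
  attr(out, "config") <- r$meta$config
  cls <- if (r$meta$kind == "ensemble") "landau_ensemble" else "landau_trajectory"
  class(out) <- c(cls, class(out))
  out
}

#' Write / read a density or quasi-potential grid as delimited text
#'
#' Long-format `(t, m, density[, phi])` records with the bin edges in the
#' metadata header.
#'
#' @param x A `landau_density` or `landau_quasipotential`.
#' @param path Output file.
#' @return `write_density()` returns `path` invisibly; `read_density()` the
#'   restored grid.
#' @export
write_density <- function(x, path) {
  kind <- if (inherits(x, "landau_quasipotential")) "quasipotential" else if (inherits(x, "landau_density")) "density" else
    rlang::abort("`x` must be a landau_density or landau_quasipotential")
  write_table_with_meta(tibble::as_tibble(x), path, kind,
                        list(m_edges = attr(x, "m_edges"),
                             n_traj = attr(x, "n_traj")))
}

#' @rdname write_density
#' @export
read_density <- function(path) {
  r <- read_table_with_meta(path)
  out <- r$data
  attr(out, "m_edges") <- r$meta$config$m_edges
  attr(out, "n_traj") <- r$meta$config$n_traj
  cls <- if (r$meta$kind == "quasipotential") {
    c("landau_quasipotential", "landau_density")
  } else {
    "landau_density"
  }
  class(out) <- c(cls, class(out))
  out
}

#' Write / read a structured report as JSON
#'
#' Serializes the list-shaped reports ([run_stability()], [run_bifurcation()],
#' [run_simulation()] summaries) to JSON at full double precision.
#'
#' @param x A report list (data frames allowed as elements).
#' @param path Output file.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   parsed list (data-frame elements as tibbles).
#' @export
write_report <- function(x, path) {
  strip <- function(el) {
    if (is_landau_model(el)) return(el[c("alpha", "beta", "gamma", "name")])
    if (is.data.frame(el)) return(el)
    if (is.list(el)) return(lapply(unclass(el), strip))
    el
  }
  jsonlite::write_json(strip(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
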