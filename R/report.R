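#' Round half away from zero
#'
#' Display rounding used by the table emitters (base R's \code{round} rounds
#' half to even). Computation is always carried in full double precision;
#' rounding happens only at the reporting boundary.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a run configuration for the command-line front end
#'
#' @param input path to a SMILES or edge-list file; \code{NULL} means the
#'   bundled drug benchmark.
#' @param format \code{"smiles"} or \code{"edgelist"}.
#' @param frr_variant FRR variant, \code{"as_stated"} or \code{"as_tabulated"}.
#' @param index_source \code{"computed"} or \code{"table2"} (QSPR predictors).
#' @param out output directory (created if absent).
#' @param digits display rounding for emitted tables.
#' @param seed integer recorded in report headers (no command is stochastic;
#'   the seed is provenance for reproducibility of the emitted files).
#' @param log_level one of "quiet", "info".
#' @return a \code{run_config} list.
#' @export
run_config <- function(input = NULL, format = c("smiles", "edgelist"),
                       frr_variant = c("as_stated", "as_tabulated"),
                       index_source = c("table2", "computed"),
                       out = ".", digits = 4L, seed = 1L,
                       log_level = c("info", "quiet")) {
  cfg <- list(input = input, format = match.arg(format),
              frr_variant = match.arg(frr_variant),
              index_source = match.arg(index_source),
              out = out, digits = as.integer(digits), seed = as.integer(seed),
              log_level = match.arg(log_level))
  class(cfg) <- "run_config"
  cfg
}

cli_log <- function(cfg, fmt, ...) {
  if (cfg$log_level != "quiet") message(sprintf(fmt, ...))
  invisible(NULL)
}

report_header <- function(cfg, what) {
  c(sprintf("# topoqspr %s", what),
    sprintf("# frr_variant: %s; index_source: %s; seed: %d; fixture: %s",
            cfg$frr_variant, cfg$index_source, cfg$seed,
            tryCatch(attr(load_eye_drugs(), "manifest")$version,
                     error = function(e) "none")))
}

write_report_csv <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

load_input_graphs <- function(cfg) {
  if (is.null(cfg$input)) {
    recs <- load_eye_drugs()
    return(list(graphs = lapply(recs, function(r)
      mol_graph_from_smiles(r$smiles, r$name)), failed = integer(0)))
  }
  if (cfg$format == "smiles") {
    failed <- integer(0)
    gs <- withCallingHandlers(
      read_smiles_file(cfg$input),
      warning = function(w) {
        cli_log(cfg, "parse failure: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(graphs = gs, failed = attr(gs, "failed"))
  } else {
    list(graphs = list(read_edge_list_file(cfg$input)), failed = integer(0))
  }
}

#' Emit the descriptor table for a set of structures
#'
#' Writes \code{indices.csv} (one row per structure, nine index columns in
#' reference-table order) under \code{cfg$out}.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return invisibly, a list with \code{path} and \code{status} (0 on
#'   success, 1 if any input line failed to parse).
#' @export
cmd_indices <- function(cfg = run_config()) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  inp <- load_input_graphs(cfg)
  if (!length(inp$graphs)) {
    stop(errorCondition("no parseable structures in input",
                        class = c("topoqspr_invalid_structure", "error")))
  }
  tab <- compute_index_table(inp$graphs, frr_variant = cfg$frr_variant)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round_half_up, digits = cfg$digits)
  path <- file.path(cfg$out, "indices.csv")
  write_report_csv(tab, path, report_header(cfg, "descriptor table"))
  cli_log(cfg, "wrote %s (%d structures, %d skipped)",
          path, nrow(tab), length(inp$failed))
  invisible(list(path = path, status = if (length(inp$failed)) 1L else 0L))
}

#' Emit the QSPR statistics tables
#'
#' Writes one CSV per index (columns Properties, N, c, m, r, r2, F, p,
#' Indicator), a 9 x 6 correlation-grid summary CSV, and a plain-text
#' listing of the 54 regression equations, all under \code{cfg$out}.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return invisibly, the character vector of files written.
#' @export
cmd_qspr <- function(cfg = run_config()) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  recs <- load_eye_drugs()
  tab <- fit_all(recs, index_source = cfg$index_source,
                 frr_variant = cfg$frr_variant)
  files <- character(0)
  for (ix in topo_indices()) {
    sub <- tab[tab$index == ix, ]
    out <- data.frame(Properties = sub$property, N = sub$n,
                      c = round_half_up(sub$c, cfg$digits),
                      m = round_half_up(sub$m, cfg$digits),
                      r = round_half_up(sub$r, cfg$digits),
                      r2 = round_half_up(sub$r2, cfg$digits),
                      F = round_half_up(sub$f_stat, cfg$digits),
                      p = round_half_up(sub$p_value, cfg$digits),
                      Indicator = sub$indicator, check.names = FALSE)
    path <- file.path(cfg$out, sprintf("qspr_%s.csv", ix))
    write_report_csv(out, path, report_header(cfg, sprintf("QSPR table: %s", ix)))
    files <- c(files, path)
  }
  grid <- stats::reshape(tab[, c("index", "property", "r")],
                         idvar = "index", timevar = "property",
                         direction = "wide")
  names(grid) <- sub("^r\\.", "", names(grid))
  grid[-1] <- lapply(grid[-1], round_half_up, digits = cfg$digits)
  gpath <- file.path(cfg$out, "correlation_grid.csv")
  write_report_csv(grid, gpath, report_header(cfg, "correlation grid"))
  epath <- file.path(cfg$out, "equations.txt")
  writeLines(c(report_header(cfg, "regression equations"),
               equation_listing(tab, cfg$digits)), epath)
  files <- c(files, gpath, epath)
  cli_log(cfg, "wrote %d QSPR report files to %s", length(files), cfg$out)
  invisible(files)
}

#' Emit the fixture validation report
#'
#' Runs \code{\link{validate_against_reference}} on the bundled benchmark
#' and writes \code{validation.csv} under \code{cfg$out}.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return invisibly, a list with \code{path}, \code{report} and
#'   \code{status} (0 iff every non-suspect cell passes).
#' @export
cmd_validate <- function(cfg = run_config()) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  rep <- validate_against_reference(frr_variant = cfg$frr_variant)
  path <- file.path(cfg$out, "validation.csv")
  write_report_csv(as.data.frame(rep), path, report_header(cfg, "validation"))
  ok <- all(rep$pass[!rep$suspect])
  cli_log(cfg, "wrote %s: %d/%d non-suspect cells pass, %d suspect cells flagged",
          path, sum(rep$pass[!rep$suspect]), sum(!rep$suspect), sum(rep$suspect))
  invisible(list(path = path, report = rep, status = if (ok) 0L else 1L))
}
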