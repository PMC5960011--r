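# Readers/writers for the table CSV/JSON dialects and the full analysis
# pipeline. Measurement names in files use ASCII: ABp for AB', ApB, ApBp.

fmt_num <- function(x) sprintf("%.17g", x)  # round-trips doubles exactly

#' Read a joint-probability table from CSV or JSON
#'
#' CSV dialect: UTF-8, header row, comma-separated, columns `measurement`
#' (AB|ABp|ApB|ApBp), `i` (1|2), `j` (1|2), `probability`; exactly 16 data
#' rows, one per slot. JSON dialect: object with fields `scheme` (axis name
#' to \[label1, label2\]), `n_participants` (int or null), and `p`
#' (measurement to \[\[p11, p12\], \[p21, p22\]\]).
#'
#' @param path File path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @return A [joint_table()] (validated for nonnegativity only; call
#'   [validate_table()] with your tolerance for normalization).
#' @export
read_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") read_table_csv(path) else read_table_json(path)
}

read_table_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, colClasses = c("character", "integer", "integer",
                                         "character"),
                    strip.white = TRUE),
    error = function(e) abort_parse(sprintf("cannot parse %s: %s", path,
                                            conditionMessage(e))))
  need <- c("measurement", "i", "j", "probability")
  if (!all(need %in% names(df))) {
    abort_parse(sprintf("missing column(s): %s",
                        paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (nrow(df) != 16L) {
    all_slots <- paste(rep(measurement_ids, each = 4L), rep(1:2, each = 2L),
                       rep(1:2, 4L))
    missing <- setdiff(all_slots, paste(df$measurement, df$i, df$j))
    abort_schema(sprintf("expected 16 rows, got %d; missing slot(s): %s",
                         nrow(df),
                         if (length(missing)) paste(missing, collapse = "; ")
                         else "none (duplicates present)"))
  }
  prob <- suppressWarnings(as.numeric(df$probability))
  if (anyNA(prob)) {
    r <- which(is.na(prob))[1L]
    abort_parse(sprintf("row %d: probability %s is not numeric", r,
                        df$probability[r]))
  }
  p <- array(NA_real_, c(2L, 2L, 4L))
  for (r in seq_len(nrow(df))) {
    m <- df$measurement[r]
    if (!m %in% measurement_ids) {
      abort_parse(sprintf("row %d: unknown measurement %s", r, m))
    }
    if (!df$i[r] %in% 1:2 || !df$j[r] %in% 1:2) {
      abort_parse(sprintf("row %d: outcome indices must be 1 or 2", r))
    }
    p[df$i[r], df$j[r], match(m, measurement_ids)] <- prob[r]
  }
  if (anyNA(p)) {
    slots <- which(is.na(p), arr.ind = TRUE)
    abort_schema(sprintf("missing slot(s): %s", paste(
      apply(slots, 1L, function(s) sprintf("(%s, %d, %d)",
                                           measurement_ids[s[3L]], s[1L], s[2L])),
      collapse = "; ")))
  }
  joint_table(p)
}

read_table_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyMatrix = TRUE),
                  error = function(e) abort_parse(sprintf(
                    "cannot parse %s: %s", path, conditionMessage(e))))
  if (is.null(obj$p)) abort_schema("JSON table must have a 'p' field")
  missing <- setdiff(measurement_ids, names(obj$p))
  if (length(missing) > 0L) {
    abort_schema(sprintf("missing measurement block(s): %s",
                         paste(missing, collapse = ", ")))
  }
  scheme <- if (!is.null(obj$scheme)) {
    do.call(windrose_scheme, lapply(obj$scheme[c("A", "Ap", "B", "Bp")],
                                    as.character))
  } else {
    windrose_scheme()
  }
  n_part <- if (!is.null(obj$n_participants) && !all(is.na(obj$n_participants))) {
    as.integer(obj$n_participants)
  }
  blocks <- lapply(obj$p[measurement_ids], function(b) {
    if (is.matrix(b)) matrix(as.numeric(b), 2L, 2L)
    else matrix(as.numeric(unlist(b)), 2L, 2L, byrow = TRUE)
  })
  joint_table(blocks, scheme = scheme, n_participants = n_part)
}

#' Write a joint-probability table to CSV or JSON
#'
#' Uses canonical formatting (17 significant digits) so that write/read
#' round trips preserve every probability bit-exactly and re-serialization
#' is byte-identical.
#'
#' @param table A [joint_table()].
#' @param path Output path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(table, "joint_table"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- as.data.frame(table)
    lines <- c("measurement,i,j,probability",
               sprintf("%s,%d,%d,%s", df$measurement, df$i, df$j,
                       fmt_num(df$probability)))
    writeLines(lines, path)
  } else {
    blocks <- lapply(measurement_ids, function(m) {
      blk <- block(table, m)
      list(c(fmt_num(blk[1, 1]), fmt_num(blk[1, 2])),
           c(fmt_num(blk[2, 1]), fmt_num(blk[2, 2])))
    })
    names(blocks) <- measurement_ids
    obj <- list(
      scheme = lapply(table$scheme, identity),
      n_participants = table$n_participants,
      p = blocks
    )
    # probabilities serialized as canonical strings to keep bytes stable;
    # read_table_json converts back with as.numeric
    json <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                             pretty = TRUE)
    writeLines(json, path)
  }
  invisible(path)
}

#' Read a rigid-rod configuration from JSON
#'
#' Dialect: object with `elastics` (measurement name A|Ap|B|Bp to
#' \{"epsilon": x, "d": y\}), `orientations` (measurement name to angle in
#' radians), and optional `order_policy`.
#'
#' @param path File path.
#' @return A [rod_config()].
#' @export
read_rod_config <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) abort_parse(sprintf(
                    "cannot parse %s: %s", path, conditionMessage(e))))
  need <- c("elastics", "orientations")
  if (!all(need %in% names(obj))) {
    abort_schema(sprintf("rod config must have fields: %s",
                         paste(need, collapse = ", ")))
  }
  elastics <- lapply(obj$elastics, function(e) {
    elastic_band(as.numeric(e$epsilon), as.numeric(e$d))
  })
  rod_config(
    elastics = elastics,
    orientations = unlist(obj$orientations),
    order_policy = if (!is.null(obj$order_policy)) obj$order_policy
                   else "uniform-mix"
  )
}

#' Run the full windrose analysis pipeline
#'
#' Orchestrates the whole chain on one input table: validate, summarize the
#' raw table, apply both symmetrization protocols and summarize each, then
#' fit the singlet quantum model to the octahedrally symmetrized table
#' (optionally to the raw table, which fails when the raw table violates
#' the marginal law).
#'
#' @param input A [joint_table()] or a path readable by [read_table()].
#' @param tol Normalization tolerance for the input table.
#' @param fit_tol Tolerance passed to [solve_directions()].
#' @param fit_raw Also attempt a quantum fit of the raw (unsymmetrized)
#'   table; an infeasible fit is recorded in the report (and flags it
#'   partial) rather than thrown.
#' @return Object of class `bellcog_report`: list with `input`, `summary`,
#'   `sym180` / `sym180_summary`, `octahedral` / `octahedral_summary`,
#'   `quantum` (a [solve_directions()] solution), optional `quantum_raw` or
#'   `quantum_raw_error`, `partial` flag, and `provenance` (package
#'   version, tolerances, timestamp).
#' @examples
#' rep <- run_full_pipeline(windrose_data(), tol = 0.011)
#' rep$octahedral_summary$absS
#' @export
run_full_pipeline <- function(input, tol = 0.011, fit_tol = 0.011,
                              fit_raw = FALSE) {
  table <- if (inherits(input, "joint_table")) input else read_table(input)
  validate_table(table, tol = tol)
  sym180 <- symmetrize_180(table)
  oct <- symmetrize_octahedral(table)
  report <- list(
    input = table,
    summary = chsh(table),
    sym180 = sym180,
    sym180_summary = chsh(sym180),
    octahedral = oct,
    octahedral_summary = chsh(oct),
    quantum = solve_directions(oct, tol = fit_tol),
    partial = FALSE,
    provenance = list(
      package = "bellcog",
      version = as.character(utils::packageVersion("bellcog")),
      tol = tol, fit_tol = fit_tol,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  if (fit_raw) {
    fit <- tryCatch(solve_directions(table, tol = fit_tol),
                    bellcog_error = function(e) e)
    if (inherits(fit, "condition")) {
      report$quantum_raw_error <- conditionMessage(fit)
      report$partial <- TRUE
    } else {
      report$quantum_raw <- fit
    }
  }
  class(report) <- "bellcog_report"
  report
}

#' @export
print.bellcog_report <- function(x, ...) {
  cat("== Coincidence-data analysis report ==\n\nInput table:\n")
  print(x$summary)
  cat("\nAfter 180-degree symmetrization:\n")
  print(x$sym180_summary)
  cat("\nAfter octahedral symmetrization:\n")
  print(x$octahedral_summary)
  cat("\nQuantum model fitted to the octahedral table:\n")
  print(x$quantum)
  if (!is.null(x$quantum_raw_error)) {
    cat(sprintf("\nRaw-table quantum fit failed: %s\n", x$quantum_raw_error))
  }
  if (x$partial) cat("\n[partial report: one or more steps failed]\n")
  invisible(x)
}
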