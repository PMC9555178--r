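#' Covariate manifest entries
#'
#' A manifest declares, for every covariate, how its raw codes map onto
#' design-matrix columns and which of the three illness-death transitions
#' (1 = recurrence, 2 = death without recurrence, 3 = death after
#' recurrence) it enters. Expansion is deterministic given the manifest:
#' columns depend only on the declared levels and their order, never on
#' the data.
#'
#' @param name covariate (and CSV column) name.
#' @param transitions integer subset of `1:3` the covariate enters.
#' @param levels raw codes as stored in the data.
#' @param labels human-readable level labels (defaults to the codes).
#' @param reference the reference code (absorbed into the baseline).
#' @param scores numeric scores for an ordinal trend covariate; the
#'   covariate enters as the single column of scores.
#' @return a covariate entry for [covariate_manifest()].
#' @name manifest-entries
NULL

new_cov <- function(name, role, levels = NULL, labels = NULL,
                    reference = NULL, scores = NULL, transitions = 1:3) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  transitions <- sort(unique(as.integer(transitions)))
  if (!all(transitions %in% 1:3)) stop("transitions must be a subset of 1:3")
  if (!is.null(levels)) {
    if (anyDuplicated(levels)) stop("duplicated levels for covariate ", name)
    if (is.null(labels)) labels <- as.character(levels)
    if (length(labels) != length(levels))
      stop("labels/levels length mismatch for covariate ", name)
  }
  if (role %in% c("binary", "categorical")) {
    if (is.null(reference)) reference <- levels[1L]
    if (!reference %in% levels)
      stop("reference level not among declared levels for covariate ", name)
    if (sum(levels == reference) != 1L)
      stop("covariate ", name, " must have exactly one reference level")
  }
  if (role == "ordinal") {
    if (is.null(scores)) scores <- seq_along(levels) - 1
    if (length(scores) != length(levels))
      stop("scores/levels length mismatch for covariate ", name)
  }
  structure(list(name = name, role = role, levels = levels, labels = labels,
                 reference = reference, scores = scores,
                 transitions = transitions),
            class = "scr_covariate")
}

#' @rdname manifest-entries
#' @export
cov_numeric <- function(name, transitions = 1:3)
  new_cov(name, "numeric", transitions = transitions)

#' @rdname manifest-entries
#' @export
cov_binary <- function(name, levels = c(0, 1), labels = NULL,
                       reference = levels[1L], transitions = 1:3)
  new_cov(name, "binary", levels = levels, labels = labels,
          reference = reference, transitions = transitions)

#' @rdname manifest-entries
#' @export
cov_ordinal <- function(name, levels, scores = seq_along(levels) - 1,
                        labels = NULL, transitions = 1:3)
  new_cov(name, "ordinal", levels = levels, labels = labels,
          scores = scores, transitions = transitions)

#' @rdname manifest-entries
#' @export
cov_categorical <- function(name, levels, labels = NULL,
                            reference = levels[1L], transitions = 1:3)
  new_cov(name, "categorical", levels = levels, labels = labels,
          reference = reference, transitions = transitions)

#' Assemble a covariate manifest
#'
#' @param ... entries built with [cov_numeric()], [cov_binary()],
#'   [cov_ordinal()] or [cov_categorical()].
#' @return an object of class `covariate_manifest`.
#' @export
#' @examples
#' m <- covariate_manifest(
#'   cov_binary("gender", levels = c(1, 2), labels = c("Female", "Male")),
#'   cov_numeric("age"))
covariate_manifest <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1]]) &&
      !inherits(entries[[1]], "scr_covariate"))
    entries <- entries[[1]]
  ok <- vapply(entries, inherits, logical(1), "scr_covariate")
  if (!all(ok)) stop("all manifest entries must be cov_* objects")
  nms <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicated covariate names in manifest")
  names(entries) <- nms
  structure(entries, class = "covariate_manifest")
}

#' @export
print.covariate_manifest <- function(x, ...) {
  cat("covariate manifest (", length(x), " covariates)\n", sep = "")
  for (e in x) {
    cat(sprintf("  %-14s %-11s transitions %s", e$name, e$role,
                paste(e$transitions, collapse = ",")))
    if (!is.null(e$levels))
      cat("  levels ", paste(e$levels, collapse = "/"), sep = "")
    if (!is.null(e$reference)) cat("  ref ", e$reference, sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Read / write a covariate manifest (YAML or JSON)
#'
#' The on-disk form is a list of covariate documents with fields
#' `name`, `role`, and where applicable `levels`, `labels`, `reference`,
#' `scores`, `transitions`.
#'
#' @param path file path; `.json` is parsed as JSON, anything else as YAML.
#' @export
read_manifest <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  entries <- lapply(raw, function(e) {
    role <- match.arg(e$role, c("numeric", "binary", "ordinal", "categorical"))
    new_cov(e$name, role,
            levels = unlist(e$levels), labels = unlist(e$labels),
            reference = if (!is.null(e$reference)) unlist(e$reference),
            scores = if (!is.null(e$scores)) as.numeric(unlist(e$scores)),
            transitions = if (is.null(e$transitions)) 1:3
                          else as.integer(unlist(e$transitions)))
  })
  covariate_manifest(entries)
}

#' @rdname read_manifest
#' @param manifest a `covariate_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  docs <- lapply(unclass(manifest), function(e)
    Filter(Negate(is.null), e[c("name", "role", "levels", "labels",
                                "reference", "scores", "transitions")]))
  names(docs) <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(docs, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(docs, path)
  invisible(path)
}

scr_required_cols <- c("subject_id", "y1", "d1", "y2", "d2")

validate_scr_rows <- function(df, manifest, time_tol = 1e-8) {
  missing <- setdiff(c(scr_required_cols, names(manifest)), names(df))
  if (length(missing))
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "))
  n <- nrow(df)
  reasons <- character(n)
  add <- function(bad, why) {
    bad <- which(bad)
    reasons[bad] <<- ifelse(nzchar(reasons[bad]),
                            paste(reasons[bad], why, sep = "; "), why)
  }
  num_ok <- function(x) is.finite(suppressWarnings(as.numeric(x)))
  y1 <- suppressWarnings(as.numeric(df$y1)); y2 <- suppressWarnings(as.numeric(df$y2))
  d1 <- suppressWarnings(as.numeric(df$d1)); d2 <- suppressWarnings(as.numeric(df$d2))
  add(!num_ok(df$y1) | !num_ok(df$y2), "non-numeric time")
  t_ok <- num_ok(df$y1) & num_ok(df$y2)
  add(t_ok & (y1 <= 0 | y2 <= 0), "nonpositive time")
  add(t_ok & y1 > y2 * (1 + time_tol), "y1 ≤ y2 violated")
  add(!(d1 %in% c(0, 1)) | !(d2 %in% c(0, 1)), "indicator not in {0,1}")
  add(t_ok & d1 %in% 0 & abs(y1 - y2) > time_tol * pmax(1, abs(y2)),
      "d1 = 0 requires y1 = y2")
  for (e in manifest) {
    v <- df[[e$name]]
    add(is.na(v), paste0("missing value in ", e$name))
    if (!is.null(e$levels))
      add(!is.na(v) & !(v %in% e$levels),
          paste0("undeclared level in ", e$name))
    else add(!is.na(v) & !num_ok(v), paste0("non-numeric value in ", e$name))
  }
  ok <- !nzchar(reasons)
  rep <- data.frame(row = which(!ok),
                    subject_id = as.character(df$subject_id[!ok]),
                    reason = reasons[!ok], stringsAsFactors = FALSE)
  list(ok = ok, report = rep)
}

#' Construct a validated semi-competing-risks dataset
#'
#' Each record carries `y1` (months to recurrence, or the censoring time),
#' `d1` (recurrence indicator), `y2` (months to death, or the censoring
#' time) and `d2` (death indicator). The semi-competing convention is
#' enforced: `0 < y1 <= y2`, and a subject without observed recurrence
#' (`d1 = 0`) has `y1 = y2` (recurrence censored at death or at
#' administrative end of follow-up). Rows violating an invariant are
#' rejected with a recorded reason, never silently dropped.
#'
#' @param records data frame with columns `subject_id`, `y1`, `d1`, `y2`,
#'   `d2` plus one column per manifest covariate.
#' @param manifest a [covariate_manifest()].
#' @return an `scr_dataset`; rejected rows are available through
#'   [validation_report()].
#' @export
scr_dataset <- function(records, manifest) {
  stopifnot(inherits(manifest, "covariate_manifest"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  v <- validate_scr_rows(records, manifest)
  acc <- records[v$ok, c(scr_required_cols, names(manifest)), drop = FALSE]
  rownames(acc) <- NULL
  acc$subject_id <- as.character(acc$subject_id)
  for (col in c("y1", "y2", "d1", "d2")) acc[[col]] <- as.numeric(acc[[col]])
  for (e in manifest)
    acc[[e$name]] <- if (is.null(e$levels) || is.numeric(e$levels))
      as.numeric(acc[[e$name]]) else as.character(acc[[e$name]])
  structure(list(records = acc, manifest = manifest, rejected = v$report),
            class = "scr_dataset")
}

#' @export
print.scr_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "scr_dataset: %d subjects (%d recurrences, %d deaths), %d covariates\n",
    nrow(r), sum(r$d1), sum(r$d2), length(x$manifest)))
  if (nrow(x$rejected))
    cat("  ", nrow(x$rejected), " row(s) rejected during validation\n", sep = "")
  invisible(x)
}

#' @export
dim.scr_dataset <- function(x) dim(x$records)

#' Validation report of a dataset read
#'
#' @param dataset an `scr_dataset`.
#' @return data frame with one row per rejected input row: original row
#'   number, subject id, and the violated invariant.
#' @export
validation_report <- function(dataset) dataset$rejected

#' Read a semi-competing-risks cohort CSV
#'
#' Expects a comma-separated UTF-8 file with a header row containing
#' `subject_id,y1,d1,y2,d2` plus the manifest's covariate columns.
#'
#' @inheritParams scr_dataset
#' @param path CSV path.
#' @return an `scr_dataset` (see [validation_report()] for rejected rows).
#' @export
read_cohort <- function(path, manifest) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  scr_dataset(df, manifest)
}

#' Write a cohort CSV at full precision
#'
#' Times are serialized with 17 significant digits so that
#' `read_cohort(write_cohort(x))` reproduces the accepted records
#' bit-identically.
#'
#' @param dataset an `scr_dataset`.
#' @param path output CSV path.
#' @export
write_cohort <- function(dataset, path) {
  df <- dataset$records
  out <- df
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- vapply(out[[col]], function(v) {
        if (is.finite(v) && v == round(v) && abs(v) < 1e15)
          sprintf("%.0f", v) else sprintf("%.17g", v)
      }, character(1))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Expand the design matrix for one transition
#'
#' One column per numeric covariate, per ordinal trend score, or per
#' non-reference category; column order follows the manifest and is
#' independent of record order. No intercept column is included (the
#' transition location parameter plays that role).
#'
#' @param dataset an `scr_dataset`.
#' @param transition 1 (recurrence), 2 (death without recurrence) or
#'   3 (death after recurrence).
#' @return numeric matrix with named columns; the column names are the
#'   canonical coefficient labels used throughout reporting.
#' @export
expand_design <- function(dataset, transition) {
  stopifnot(inherits(dataset, "scr_dataset"), transition %in% 1:3)
  df <- dataset$records
  cols <- list()
  for (e in dataset$manifest) {
    if (!(transition %in% e$transitions)) next
    v <- df[[e$name]]
    if (!is.null(e$levels) && any(!v %in% e$levels))
      stop("level(s) observed in data but absent from manifest for ",
           e$name, ": ",
           paste(unique(v[!v %in% e$levels]), collapse = ", "))
    switch(e$role,
      numeric = { cols[[e$name]] <- as.numeric(v) },
      ordinal = {
        cols[[e$name]] <- e$scores[match(v, e$levels)]
      },
      binary = ,
      categorical = {
        keep <- which(e$levels != e$reference)
        for (k in keep)
          cols[[paste0(e$name, ":", e$labels[k])]] <-
            as.numeric(v == e$levels[k])
      })
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(df), ncol = 0)
  dimnames(X) <- list(NULL, as.character(names(cols)))
  X
}
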