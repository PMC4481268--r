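# Domain types and I/O for IAT trial tables and criterion panels.
#
# Canonical long format: one row per trial with columns subject, session,
# pairing (compatible/incompatible), phase (practice/test), latency (ms),
# error (logical), and optional block_index. Within-block row order is the
# presentation order and is preserved (odd/even reliability splits rely on
# it).

.PAIRINGS <- c("compatible", "incompatible")
.PHASES   <- c("practice", "test")

#' Construct a validated IAT trial table
#'
#' @param trials A data.frame with columns `subject`, `pairing`, `phase`,
#'   `latency` (ms), `error` (logical); optional `session` (integer >= 1,
#'   defaults to 1) and `block_index`.
#' @param built_in_penalty Logical: did the IAT procedure force error
#'   correction, so that recorded latencies already contain the penalty?
#' @param dataset_label Free-text label carried through to rank tables.
#' @return A data.frame of class `iat_trials` with attributes
#'   `built_in_penalty` and `dataset_label`.
#' @export
iat_trials <- function(trials, built_in_penalty = FALSE, dataset_label = "") {
  stopifnot(is.data.frame(trials))
  req <- c("subject", "pairing", "phase", "latency", "error")
  miss <- setdiff(req, names(trials))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(trials)
  if (!"session" %in% names(df)) df$session <- 1L
  df$subject <- as.character(df$subject)
  df$session <- as.integer(df$session)
  df$pairing <- as.character(df$pairing)
  df$phase   <- as.character(df$phase)
  df$latency <- as.numeric(df$latency)
  df$error   <- .parse_flag(df$error)

  bad <- which(!df$pairing %in% .PAIRINGS)
  if (length(bad)) stop("invalid pairing at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        call. = FALSE)
  bad <- which(!df$phase %in% .PHASES)
  if (length(bad)) stop("invalid phase at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        call. = FALSE)
  bad <- which(!is.finite(df$latency) | df$latency <= 0)
  if (length(bad)) stop("non-positive or unparseable latency at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        call. = FALSE)
  bad <- which(is.na(df$error))
  if (length(bad)) stop("unparseable error flag at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        call. = FALSE)
  if (any(df$session < 1L)) stop("session indices must be >= 1", call. = FALSE)

  for (s in unique(df$subject)) {
    pr <- unique(df$pairing[df$subject == s])
    if (!all(.PAIRINGS %in% pr)) {
      stop("subject ", s, " lacks trials in pairing: ",
           paste(setdiff(.PAIRINGS, pr), collapse = ", "), call. = FALSE)
    }
  }

  canon_order <- c("subject", "session", "pairing", "phase", "latency",
                   "error")
  df <- df[c(canon_order, setdiff(names(df), canon_order))]
  rownames(df) <- NULL
  structure(df, class = c("iat_trials", "data.frame"),
            built_in_penalty = isTRUE(built_in_penalty),
            dataset_label = as.character(dataset_label))
}

.parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(ifelse(x %in% c(0, 1), x == 1, NA))
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes", "error")] <- TRUE
  out[x %in% c("0", "false", "f", "no", "correct")] <- FALSE
  out
}

#' Read an IAT trial table from CSV/TSV
#'
#' Column names in the file are mapped onto the canonical schema through a
#' dialect map, so heterogeneous sources can be read without renaming files.
#'
#' @param path Path to a delimited file with a header row. `.tsv`/`.tab`
#'   files are read tab-separated, everything else comma-separated.
#' @param dialect Named character vector mapping canonical names
#'   (`subject`, `pairing`, `phase`, `latency_ms`, `error`, and optionally
#'   `session`, `block_index`) to the file's column names. Defaults to the
#'   identity map.
#' @param built_in_penalty,dataset_label Passed to [iat_trials()].
#' @return An `iat_trials` table.
#' @export
read_trials <- function(path, dialect = NULL, built_in_penalty = FALSE,
                        dataset_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  canon <- c(subject = "subject", pairing = "pairing", phase = "phase",
             latency_ms = "latency_ms", error = "error",
             session = "session", block_index = "block_index")
  if (!is.null(dialect)) canon[names(dialect)] <- dialect
  req <- c("subject", "pairing", "phase", "latency_ms", "error")
  miss <- req[!canon[req] %in% names(raw)]
  if (length(miss)) {
    stop("configuration error: column(s) not found in ", basename(path), ": ",
         paste(canon[miss], collapse = ", "), call. = FALSE)
  }
  df <- data.frame(subject = raw[[canon["subject"]]],
                   pairing = raw[[canon["pairing"]]],
                   phase   = raw[[canon["phase"]]],
                   latency = suppressWarnings(as.numeric(raw[[canon["latency_ms"]]])),
                   error   = raw[[canon["error"]]],
                   stringsAsFactors = FALSE)
  if (canon["session"] %in% names(raw)) df$session <- raw[[canon["session"]]]
  if (canon["block_index"] %in% names(raw)) {
    df$block_index <- raw[[canon["block_index"]]]
  }
  iat_trials(df, built_in_penalty = built_in_penalty,
             dataset_label = dataset_label)
}

#' Write an IAT trial table to CSV/TSV
#'
#' Round-trips with [read_trials()] field for field.
#'
#' @param table An `iat_trials` table.
#' @param path Output path; `.tsv` writes tab-separated.
#' @return `path`, invisibly.
#' @export
write_trials <- function(table, path) {
  stopifnot(inherits(table, "iat_trials"))
  out <- as.data.frame(table)
  names(out)[names(out) == "latency"] <- "latency_ms"
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-subject structural report
#'
#' Counts trials per subject x pairing x phase (and session) and flags
#' subjects lacking either pairing or either phase. A missing phase only
#' matters when scoring distinguishes practice from test trials.
#'
#' @param table An `iat_trials` table.
#' @return A data.frame with one row per subject x session x pairing x phase
#'   combination (`n` = trial count, zero rows included), with attribute
#'   `flags`: a data.frame of subjects missing a pairing or phase.
#' @export
validate_structure <- function(table) {
  stopifnot(inherits(table, "iat_trials"))
  if (nrow(table) == 0L) stop("empty trial table", call. = FALSE)
  df <- as.data.frame(table)
  grid <- expand.grid(subject = unique(df$subject),
                      session = sort(unique(df$session)),
                      pairing = .PAIRINGS, phase = .PHASES,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  cnt <- stats::aggregate(list(n = df$latency),
                          df[c("subject", "session", "pairing", "phase")],
                          FUN = length)
  rep_ <- merge(grid, cnt, all.x = TRUE, sort = TRUE)
  rep_$n[is.na(rep_$n)] <- 0L
  rep_ <- rep_[order(rep_$subject, rep_$session, rep_$pairing, rep_$phase), ]
  rownames(rep_) <- NULL

  by_sub <- split(rep_, rep_[c("subject", "session")], drop = TRUE)
  flags <- do.call(rbind, lapply(by_sub, function(g) {
    missing_pairing <- sapply(.PAIRINGS, function(p) sum(g$n[g$pairing == p]) == 0L)
    missing_phase <- sapply(.PHASES, function(p) sum(g$n[g$phase == p]) == 0L)
    if (!any(missing_pairing) && !any(missing_phase)) return(NULL)
    data.frame(subject = g$subject[1], session = g$session[1],
               missing = paste(c(.PAIRINGS[missing_pairing],
                                 .PHASES[missing_phase]), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(flags)) {
    flags <- data.frame(subject = character(0), session = integer(0),
                        missing = character(0))
  }
  rownames(flags) <- NULL
  structure(rep_, flags = flags)
}

#' Construct a criterion panel
#'
#' One row per subject, one column per criterion measure; every measure is
#' oriented so that higher values indicate a stronger target-consistent
#' preference. Each measure is assigned one role: `direct` (self-report),
#' `indirect` (other latency-based measures), or `behavioral` (predictive
#' criteria).
#'
#' @param data A data.frame with a `subject` column and numeric measure
#'   columns.
#' @param roles Named character vector mapping each measure column to
#'   `"direct"`, `"indirect"` or `"behavioral"`.
#' @return A data.frame of class `iat_criteria` with attribute `roles`.
#' @export
iat_criteria <- function(data, roles) {
  stopifnot(is.data.frame(data), "subject" %in% names(data))
  measures <- setdiff(names(data), "subject")
  miss <- setdiff(measures, names(roles))
  if (length(miss)) stop("no role declared for measure(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  roles <- roles[measures]
  bad <- !roles %in% c("direct", "indirect", "behavioral")
  if (any(bad)) stop("invalid role(s): ",
                     paste(unique(roles[bad]), collapse = ", "), call. = FALSE)
  df <- as.data.frame(data)
  df$subject <- as.character(df$subject)
  for (m in measures) df[[m]] <- as.numeric(df[[m]])
  structure(df, class = c("iat_criteria", "data.frame"), roles = roles)
}

#' Read a criterion panel (CSV + JSON role sidecar)
#'
#' @param path CSV with a `subject` column and one column per measure.
#' @param roles_path JSON file mapping each measure name to its role
#'   (`direct`, `indirect`, `behavioral`).
#' @return An `iat_criteria` panel.
#' @export
read_criteria <- function(path, roles_path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!file.exists(roles_path)) stop("file not found: ", roles_path,
                                     call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  roles <- unlist(jsonlite::read_json(roles_path, simplifyVector = TRUE))
  iat_criteria(df, roles)
}

#' Write a criterion panel and its role sidecar
#'
#' @param panel An `iat_criteria` panel.
#' @param path CSV output path.
#' @param roles_path JSON sidecar path; defaults to `<path>.roles.json`.
#' @return `path`, invisibly.
#' @export
write_criteria <- function(panel, path,
                           roles_path = paste0(path, ".roles.json")) {
  stopifnot(inherits(panel, "iat_criteria"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  jsonlite::write_json(as.list(attr(panel, "roles")), roles_path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @export
print.iat_trials <- function(x, ...) {
  cat(sprintf("<iat_trials> %d trials, %d subject(s), %d session(s), %s\n",
              nrow(x), length(unique(x$subject)),
              length(unique(x$session)),
              if (attr(x, "built_in_penalty")) "built-in penalty"
              else "no built-in penalty"))
  NextMethod()
}
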