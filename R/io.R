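TRIAL_COLUMNS <- c("subject", "session", "phase", "trial", "a1", "s2", "a2",
                   "outcome", "transition", "aborted", "rt")

#' Read a trial-log CSV
#'
#' Reads the standard trial-log format (one row per trial, mandatory
#' header): `subject,session,phase,trial,a1,s2,a2,outcome,transition,`
#' `aborted,rt`, with `a1`/`a2` in `{L,R}`, `s2` in `{S1,S2}`, `outcome`
#' in `{0,1}`, `transition` in `{common,rare}`, `aborted` in `{0,1}`, `rt`
#' empty or decimal seconds, and `a2` empty exactly when `aborted == 1`.
#' An optional trailing `rewarding` column (the simulator's record of the
#' rewarding stage-2 state) is preserved when present. Every violation is
#' reported with its row number.
#'
#' @param path Path to the CSV file.
#' @return A validated trial data.frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("trial log is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  fail <- function(rows, what) {
    stop(sprintf("trial-log validation: %s (row %s)", what,
                 paste(utils::head(rows, 5L), collapse = ", ")))
  }
  chk <- function(ok, what) if (!all(ok)) fail(which(!ok), what)
  df$a2[df$a2 == ""] <- NA_character_
  df$rt[df$rt == ""] <- NA_character_
  chk(df$a1 %in% c("L", "R"), "a1 must be L or R")
  chk(df$s2 %in% c("S1", "S2"), "s2 must be S1 or S2")
  chk(df$outcome %in% c("0", "1"), "outcome must be 0 or 1")
  chk(df$transition %in% c("common", "rare"), "transition must be common or rare")
  chk(df$aborted %in% c("0", "1"), "aborted must be 0 or 1")
  chk(is.na(df$a2) | df$a2 %in% c("L", "R"), "a2 must be L, R or empty")
  chk(!(df$aborted == "1") | is.na(df$a2), "a2 must be empty on aborted rows")
  chk(!(df$aborted == "0") | !is.na(df$a2), "a2 missing on non-aborted row")
  chk(!(df$aborted == "1") | df$outcome == "0", "aborted rows cannot be rewarded")
  suppressWarnings({
    df$session <- as.integer(df$session)
    df$trial <- as.integer(df$trial)
    df$outcome <- as.integer(df$outcome)
    df$aborted <- as.integer(df$aborted)
    df$rt <- as.numeric(df$rt)
  })
  chk(!is.na(df$session), "session must be an integer")
  chk(!is.na(df$trial), "trial must be an integer")
  chk(is.na(df$rt) | df$rt >= 0, "rt must be non-negative seconds")
  if ("rewarding" %in% names(df)) {
    chk(df$rewarding %in% c("S1", "S2"), "rewarding must be S1 or S2")
  }
  keep <- c(TRIAL_COLUMNS, intersect("rewarding", names(df)))
  df[keep]
}

#' Write a trial-log CSV
#'
#' Canonical dialect: comma-separated, UTF-8, mandatory header, no
#' quoting, missing `a2`/`rt` as empty fields. `read_trials()` followed by
#' `write_trials()` reproduces a canonical file byte for byte.
#'
#' @param trials Trial data.frame.
#' @param path Output path.
#' @export
write_trials <- function(trials, path) {
  keep <- c(TRIAL_COLUMNS, intersect("rewarding", names(trials)))
  utils::write.table(trials[keep], path, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write / read the ground-truth sidecar of a synthetic cohort
#'
#' A flat `key=value` text format (dotted keys) holding the master seed
#' and every subject's drawn parameters, sufficient -- together with the
#' cohort configuration -- to regenerate the dataset bit-exactly.
#'
#' @param ground_truth The `ground_truth` element of [generate_cohort()].
#' @param path Output path (conventionally `<trials>.truth.txt`).
#' @return `write_ground_truth`: the path, invisibly.
#'   `read_ground_truth`: a named list of keys and values.
#' @export
write_ground_truth <- function(ground_truth, path) {
  lines <- c(paste0("seed=", ground_truth$seed))
  for (sub in names(ground_truth$params)) {
    for (fam in names(ground_truth$params[[sub]])) {
      p <- ground_truth$params[[sub]][[fam]]
      lines <- c(lines, sprintf("param.%s.%s.%s=%.17g", sub, fam, names(p), p))
    }
  }
  seeds <- ground_truth$session_seeds
  for (sub in rownames(seeds)) {
    lines <- c(lines, sprintf("session_seed.%s.%d=%d", sub,
                              seq_len(ncol(seeds)), seeds[sub, ]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) x[2]), vapply(kv, `[[`, "", 1))
}
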