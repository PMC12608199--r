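# File formats.  All real numbers are serialised with 12 significant digits;
# temperatures in reports are additionally echoed at 6 decimals.

fmt_real <- function(x) formatC(x, digits = 12, format = "g")

#' Read and write densities of states as TSV
#'
#' Two columns (`energy`, `count`) preceded by a header line
#' `# seq=<string> params=<eHH,eHP,ePP> N=<n> mode=<mode>`.
#'
#' @param dos an `hp_dos` object.
#' @param path file path.
#' @return `read_dos()` returns an `hp_dos`; counts are value-exact.
#' @export
write_dos <- function(dos, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- attr(dos, "params")
  writeLines(sprintf("# seq=%s params=%d,%d,%d N=%d mode=%s",
                     attr(dos, "sequence"), p[1], p[2], p[3],
                     attr(dos, "n"), attr(dos, "mode")), con)
  writeLines("energy\tcount", con)
  writeLines(sprintf("%d\t%.0f", dos$energy, dos$count), con)
  invisible(path)
}

#' @rdname write_dos
#' @export
read_dos <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")][1]
  fields <- regmatches(hdr, gregexpr("[a-zA-Z]+=[^ ]+", hdr))[[1]]
  kv <- setNames(sub("^[a-zA-Z]+=", "", fields), sub("=.*$", "", fields))
  body <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                     sep = "\t", colClasses = c("integer", "numeric"))
  params <- as.integer(strsplit(kv[["params"]], ",")[[1]])
  structure(body, class = c("hp_dos", "data.frame"),
            sequence = unname(kv[["seq"]]), params = params,
            n = as.integer(kv[["N"]]), mode = unname(kv[["mode"]]))
}

# screen results TSV: sequence, e0, n_e0 (+ completeness marker)
write_screen <- function(screen, path, complete = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# screen n_total=%s complete=%s",
                     fmt_real(attr(screen, "n_total") %||% NA),
                     if (complete) "yes" else "no"), con)
  writeLines("sequence\te0\tn_e0", con)
  if (nrow(screen))
    writeLines(sprintf("%s\t%d\t%.0f", screen$sequence,
                       as.integer(screen$e0), screen$n_e0), con)
  invisible(path)
}

read_screen <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")][1]
  body <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                     sep = "\t", colClasses = c("character", "integer", "numeric"))
  attr(body, "complete") <- grepl("complete=yes", hdr, fixed = TRUE)
  body
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write zeros, bands and component peaks as CSV
#'
#' One row per root: `re, im, modulus, arg, residual, band, peak_T,
#' peak_height, paired`.  The per-component peak columns are mapped onto
#' both members of a conjugate pair.
#'
#' @param zeros an `hp_zeros` object (after [band_zeros()]).
#' @param components the matching [decompose()] output.
#' @param path file path.
#' @export
write_zeros_csv <- function(zeros, components, path) {
  peak_T <- peak_h <- rep(NA_real_, nrow(zeros))
  paired <- rep(NA, nrow(zeros))
  for (i in seq_len(nrow(components))) {
    hit <- abs(zeros$re - components$re[i]) < 1e-12 * pmax(1, abs(components$re[i])) &
      abs(abs(zeros$im) - components$im[i]) < 1e-12 * pmax(1, components$im[i])
    peak_T[hit] <- components$peak_T[i]
    peak_h[hit] <- components$peak_height[i]
    paired[hit] <- components$paired[i]
  }
  df <- data.frame(re = fmt_real(zeros$re), im = fmt_real(zeros$im),
                   modulus = fmt_real(zeros$modulus), arg = fmt_real(zeros$arg),
                   residual = fmt_real(zeros$residual), band = zeros$band,
                   peak_T = fmt_real(peak_T), peak_height = fmt_real(peak_h),
                   paired = paired)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_zeros_csv
#' @export
read_zeros_csv <- function(path) {
  read.table(path, sep = ",", header = TRUE,
             colClasses = c(rep("numeric", 5), "character",
                            "numeric", "numeric", "logical"))
}

#' Transition report JSON
#'
#' Serialises an [hp_transitions] report (after [classify_foldability()])
#' with its full configuration echo: `t_theta`, `t_f`, `sigma`,
#' `crossover_score`, `group`, `gap_factor`, `threshold`, `precision`,
#' `sequence`, `params`, `version`.
#'
#' @param report an `hp_transitions` object.
#' @param path file path.
#' @export
write_transition_report <- function(report, path) {
  obj <- list(sequence = report$sequence,
              t_theta = round(report$t_theta, 6),
              t_f = if (is.na(report$t_f)) NULL else round(report$t_f, 6),
              sigma = report$sigma,
              crossover_score = report$crossover_score,
              group = report$group,
              n_bands = report$n_bands,
              gap_factor = report$gap_factor,
              threshold = report$threshold,
              precision = report$precision,
              version = as.character(packageVersion("hpfold")))
  jsonlite::write_json(obj[!vapply(obj, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(path)
}

#' @rdname write_transition_report
#' @export
read_transition_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a mean first-passage-time curve as CSV
#'
#' Columns `T, mean_fpt, sem, n_runs, n_censored`; the optional per-run
#' detail (attribute `runs`) is written as a sidecar TSV when `runs_path`
#' is given.
#'
#' @param curve an `hp_fpt_curve`.
#' @param path CSV path.
#' @param runs_path optional TSV path for the per-run table.
#' @export
write_fpt_csv <- function(curve, path, runs_path = NULL) {
  df <- data.frame(T = fmt_real(curve$temperature),
                   mean_fpt = fmt_real(curve$mean_fpt),
                   sem = fmt_real(curve$sem),
                   n_runs = curve$n_runs, n_censored = curve$n_censored)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  runs <- attr(curve, "runs")
  if (!is.null(runs_path) && !is.null(runs)) {
    out <- data.frame(run = runs$run, temperature = fmt_real(runs$temperature),
                      fpt = fmt_real(runs$fpt), events = sprintf("%.0f", runs$events),
                      censored = runs$censored)
    write.table(out, runs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
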