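#' HP sequences
#'
#' An HP sequence is an ordered string of residue labels over the two-letter
#' alphabet \{H, P\}: H for hydrophobic and P for polar beads.  Chains must
#' have at least three residues, the shortest length at which nonconsecutive
#' contacts and corner moves are possible.
#'
#' @param x a single character string such as `"HPPH"`, or an `hp_sequence`.
#' @return an object of class `hp_sequence`.
#' @examples
#' s <- hp_sequence("HPPHPPPHPHPPHPHP")
#' length(s)
#' @export
hp_sequence <- function(x) {
  if (inherits(x, "hp_sequence")) return(x)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("an HP sequence must be a single character string", call. = FALSE)
  res <- strsplit(toupper(trimws(x)), "", fixed = TRUE)[[1]]
  bad <- which(!res %in% c("H", "P"))
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d (alphabet is {H, P})",
                 res[bad[1]], bad[1]), call. = FALSE)
  if (length(res) < 3L)
    stop("HP chains must have at least 3 residues", call. = FALSE)
  structure(list(residues = res), class = "hp_sequence")
}

#' @export
length.hp_sequence <- function(x) length(x$residues)

#' @export
as.character.hp_sequence <- function(x, ...) paste(x$residues, collapse = "")

#' @export
format.hp_sequence <- function(x, ...) as.character(x)

#' @export
print.hp_sequence <- function(x, ...) {
  cat(sprintf("<hp_sequence> %s (N = %d, %d H)\n", as.character(x),
              length(x), sum(x$residues == "H")))
  invisible(x)
}

# internal residue-type coding used by the compiled kernels: 0 = H, 1 = P
hp_types <- function(seq) as.integer(hp_sequence(seq)$residues == "P")

#' Read and write HP sequences as plain text
#'
#' One sequence per line; FASTA-style header lines (starting with `>`) and
#' blank lines are ignored, so a FASTA file whose bodies are HP strings is
#' accepted as-is.
#'
#' @param path file path.
#' @param seqs a list of [hp_sequence()] objects (or strings) to write.
#' @return `read_hp_sequences()` returns a list of `hp_sequence` objects.
#' @export
read_hp_sequences <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, ">") & !startsWith(lines, "#")]
  lapply(lines, hp_sequence)
}

#' @rdname read_hp_sequences
#' @export
write_hp_sequences <- function(seqs, path) {
  if (inherits(seqs, "hp_sequence") || is.character(seqs)) seqs <- list(seqs)
  writeLines(vapply(seqs, function(s) as.character(hp_sequence(s)), ""), path)
  invisible(path)
}

#' Contact-energy parameters of the HP model
#'
#' The three contact energies must satisfy `eHH < eHP < ePP < 0` and
#' `eHH + ePP < 2 * eHP`, which makes H-H contacts dominant and mixing
#' unfavourable relative to demixing.  The default integer set
#' (-10, -6, -3) keeps every conformation energy an integer, so the
#' partition function is a polynomial in `x = exp(1/kT)`.
#'
#' @param eHH,eHP,ePP integer contact energies.
#' @return an object of class `hp_params`.
#' @examples
#' hp_params()           # the default (-10, -6, -3)
#' @export
hp_params <- function(eHH = -10L, eHP = -6L, ePP = -3L) {
  e <- c(eHH = eHH, eHP = eHP, ePP = ePP)
  if (any(!is.finite(e)) || any(e != round(e)))
    stop("contact energies must be integers", call. = FALSE)
  e <- as.integer(round(e))
  if (!(e[1] < e[2] && e[2] < e[3]))
    stop("contact energies must satisfy eHH < eHP < ePP", call. = FALSE)
  if (!(e[1] + e[3] < 2L * e[2]))
    stop("contact energies must satisfy eHH + ePP < 2*eHP", call. = FALSE)
  if (e[3] >= 0L)
    stop("contact energies must be negative (attractive contacts)", call. = FALSE)
  structure(list(eHH = e[[1]], eHP = e[[2]], ePP = e[[3]]), class = "hp_params")
}

#' @export
print.hp_params <- function(x, ...) {
  cat(sprintf("<hp_params> eHH = %d, eHP = %d, ePP = %d\n", x$eHH, x$eHP, x$ePP))
  invisible(x)
}

# internal: parameter triple as an integer vector for the C++ kernels
hp_eps <- function(params) {
  params <- if (inherits(params, "hp_params")) params else do.call(hp_params, as.list(params))
  c(params$eHH, params$eHP, params$ePP)
}
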