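# File interchange: PDB output (for visual inspection purposes), the
# 3DNA-style .par parameter table dialect, and two-column decay text files.

#' Write a model to a PDB file
#'
#' Emits standard fixed-width ATOM records with strand I as chain A and
#' strand II as chain B (chain B listed 5'->3'). The shipped residue
#' templates omit the sugar-phosphate backbone, so the file is a reduced
#' base-and-probe representation intended for visual inspection purposes.
#'
#' @param model An `na_model` with atoms.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "na_model"))
  at <- model$atoms
  if (is.null(at) || nrow(at) == 0) stop("model has no atoms", call. = FALSE)
  n <- n_pairs(model)
  a1 <- at[at$strand == "I", ]
  a1 <- a1[order(a1$pos), ]
  a2 <- at[at$strand == "II", ]
  a2 <- a2[order(-a2$pos), ]         # chain B runs 5'->3' (descending pos)
  a2$resno <- n + (n - a2$pos + 1L)
  a1$resno <- a1$pos
  recs <- character(0)
  serial <- 0L
  fmt_res <- function(r) sprintf("%3s", substr(r, 1, 3))
  for (blk in list(list(a = a1, ch = "A"), list(a = a2, ch = "B"))) {
    a <- blk$a
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      recs <- c(recs, sprintf(
        "ATOM  %5d %-4s%4s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, substr(a$name[i], 1, 4), fmt_res(a$resname[i]), blk$ch,
        a$resno[i], a$x[i], a$y[i], a$z[i], 1, 0, a$element[i]
      ))
    }
    recs <- c(recs, "TER")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "REMARK   generated by basefret (reduced base representation,",
    "REMARK   for visual inspection purposes)", recs, "END"
  ), con)
  invisible(path)
}

#' Write a parameter table file
#'
#' The `.par` dialect: a header line with the pair count, a separator line,
#' a column-name comment and then one row per base pair carrying the pair
#' label, the six intra-pair parameters (shear...opening) and the six step
#' parameters (shift...twist) leading into that pair. The first row's step
#' block is zero by convention and ignored on read.
#'
#' @param sequence Strand-I sequence (string or character vector).
#' @param step_table Data frame/tibble with n-1 rows of step parameters.
#' @param pair_table Data frame/tibble with n rows of pair parameters; ideal
#'   (zero) pairs if `NULL`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_par <- function(sequence, step_table, pair_table = NULL, path) {
  seq1 <- split_sequence(sequence)
  n <- length(seq1)
  step_table <- as.data.frame(step_table)
  if (nrow(step_table) != n - 1L) {
    stop("step_table must have one row per step (n-1)", call. = FALSE)
  }
  if (is.null(pair_table)) {
    pair_table <- as.data.frame(matrix(0, n, 6))
  }
  pair_table <- as.data.frame(pair_table)
  if (nrow(pair_table) != n) {
    stop("pair_table must have one row per pair (n)", call. = FALSE)
  }
  labels <- paste0(seq1, "-", complement_base(seq1))
  steps <- rbind(rep(0, 6), as.matrix(step_table[, 1:6]))
  pairs <- as.matrix(pair_table[, 1:6])
  rows <- vapply(seq_len(n), function(i) {
    paste0(sprintf("%-6s", labels[i]),
           paste(sprintf("%10.4f", c(pairs[i, ], steps[i, ])), collapse = ""))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("%5d # base-pairs", n),
    "    0 # ***local base-pair & step parameters***",
    paste0("#       Shear    Stretch   Stagger    Buckle  Prop-Tw",
           "   Opening     Shift     Slide      Rise      Tilt      Roll     Twist"),
    rows
  ), con)
  invisible(path)
}

#' Read a parameter table file
#'
#' Parses the `.par` dialect written by [write_par()] (and by 3DNA-style
#' analysis tools): pair labels plus twelve numeric columns per row. The
#' first row's step block is ignored.
#'
#' @param path Path to a `.par` file.
#' @return A list with `sequence` (strand-I string), `step_table` (tibble,
#'   n-1 rows: shift, slide, rise, tilt, roll, twist) and `pair_table`
#'   (tibble, n rows: shear, stretch, stagger, buckle, propeller, opening),
#'   directly consumable by [build_duplex()].
#' @export
read_par <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("malformed parameter file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1]))
  if (is.na(n) || n < 1) {
    stop("line 1: expected a base-pair count", call. = FALSE)
  }
  body <- lines[-(1:2)]
  keep <- !grepl("^\\s*#", body) & nzchar(trimws(body))
  body_idx <- which(keep)
  body <- body[keep]
  if (length(body) != n) {
    stop(sprintf("expected %d data rows, found %d", n, length(body)),
         call. = FALSE)
  }
  seq1 <- character(n)
  vals <- matrix(NA_real_, n, 12)
  for (i in seq_len(n)) {
    tk <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tk) != 13L) {
      stop(sprintf("line %d: expected 13 columns, found %d",
                   body_idx[i] + 2L, length(tk)), call. = FALSE)
    }
    seq1[i] <- substr(tk[1], 1, 1)
    v <- suppressWarnings(as.numeric(tk[-1]))
    if (any(is.na(v))) {
      stop(sprintf("line %d: non-numeric parameter", body_idx[i] + 2L),
           call. = FALSE)
    }
    vals[i, ] <- v
  }
  pair_table <- tibble::as_tibble(as.data.frame(vals[, 1:6, drop = FALSE]))
  names(pair_table) <- c("shear", "stretch", "stagger", "buckle",
                         "propeller", "opening")
  step_table <- tibble::as_tibble(as.data.frame(vals[-1, 7:12, drop = FALSE]))
  names(step_table) <- c("shift", "slide", "rise", "tilt", "roll", "twist")
  list(sequence = paste(seq1, collapse = ""), step_table = step_table,
       pair_table = pair_table)
}

#' Read and write two-column decay files
#'
#' Decay and instrument-response curves are exchanged as whitespace-delimited
#' text with `#` comment headers: time (ns) and counts per channel.
#'
#' @param curve A [decay_curve()].
#' @param path File path.
#' @param comment Optional extra header lines (without the leading `#`).
#' @return `write_decay()` invisibly returns the path; `read_decay()` returns
#'   a [decay_curve()].
#' @export
write_decay <- function(curve, path, comment = character()) {
  stopifnot(inherits(curve, "decay_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# ", c("time_ns counts", comment)),
    sprintf("%.7f %.8g", curve$time, curve$counts)
  ), con)
  invisible(path)
}

#' @rdname write_decay
#' @export
read_decay <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.table(path, comment.char = "#", col.names = c("time", "counts"))
  decay_curve(time = d$time, counts = d$counts)
}
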