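# Fixed-column PDB v3.3 ATOM/HETATM layout. The reader keeps every raw line
# verbatim so that writing is byte-identical except for fields this package
# deliberately edits (the B-factor, columns 61-66).

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA_123 <- stats::setNames(names(AA_321), unname(AA_321))

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records from fixed columns of a PDB file into a
#' structure model. All lines (headers, TER, END, ...) are preserved verbatim
#' so that [write_pdb()] round-trips the file byte-for-byte.
#'
#' @param path path to a PDB file (ignored when `text` is given).
#' @param text optional character scalar or vector holding the file content.
#' @return An object of class `pdb_model`: a list with `lines` (all raw
#'   lines) and `atoms`, a `data.frame` with one row per ATOM/HETATM record
#'   (`line`, `record`, `serial`, `atom_name`, `alt_loc`, `res_name`,
#'   `chain`, `res_num`, `ins_code`, `x`, `y`, `z`, `occupancy`, `b_factor`).
#' @export
read_pdb <- function(path, text = NULL) {
  lines <- if (!is.null(text)) {
    if (length(text) == 1L && grepl("\n", text)) {
      strsplit(text, "\n", fixed = TRUE)[[1]]
    } else text
  } else readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) {
    stop("empty structure: no ATOM records found", call. = FALSE)
  }
  idx <- which(is_atom)
  f <- function(lo, hi) trimws(substr(lines[idx], lo, hi))
  num <- function(lo, hi, what) {
    raw <- substr(lines[idx], lo, hi)
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & nzchar(trimws(raw))
    empty <- !nzchar(trimws(raw))
    if (what %in% c("x", "y", "z") && any(bad | empty)) {
      stop("PDB parse error: non-numeric ", what, " coordinate at line ",
           idx[which(bad | empty)[1]], call. = FALSE)
    }
    val
  }
  atoms <- data.frame(
    line = idx,
    record = trimws(rec[idx]),
    serial = suppressWarnings(as.integer(f(7, 11))),
    atom_name = f(13, 16),
    alt_loc = substr(lines[idx], 17, 17),
    res_name = f(18, 20),
    chain = substr(lines[idx], 22, 22),
    res_num = suppressWarnings(as.integer(f(23, 26))),
    ins_code = substr(lines[idx], 27, 27),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occupancy = num(55, 60, "occupancy"),
    b_factor = num(61, 66, "b_factor"),
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("PDB parse error: non-finite coordinates", call. = FALSE)
  }
  structure(list(lines = lines, atoms = atoms), class = "pdb_model")
}

#' @export
print.pdb_model <- function(x, ...) {
  res <- unique(paste(x$atoms$chain, x$atoms$res_num))
  cat("<pdb_model> ", nrow(x$atoms), " atoms, ", length(res), " residues, ",
      "chains: ", paste(unique(x$atoms$chain), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Write a PDB structure
#'
#' Emits the model's lines verbatim. Edits made through [annotate_bfactor()]
#' are already reflected in the stored lines, so coordinates, occupancies and
#' record order are untouched.
#'
#' @param model a `pdb_model`.
#' @param path output file; when `NULL` the lines are returned.
#' @return invisibly (or visibly when `path` is `NULL`), the lines.
#' @export
write_pdb <- function(model, path = NULL) {
  stopifnot(inherits(model, "pdb_model"))
  if (is.null(path)) return(model$lines)
  writeLines(model$lines, path)
  invisible(model$lines)
}

#' Residue-level view of a model
#'
#' One row per residue (first-atom order), with the residue's first-atom
#' B-factor — the per-residue value under both the pLDDT convention and this
#' package's score painting.
#'
#' @param model a `pdb_model`.
#' @param chain optional chain selector; default = first chain in the file.
#' @return `data.frame`: `chain`, `res_num`, `res_name`, `b_factor`.
#' @export
pdb_residues <- function(model, chain = NULL) {
  atoms <- model$atoms[model$atoms$record == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  first <- !duplicated(atoms$res_num)
  out <- atoms[first, c("chain", "res_num", "res_name", "b_factor")]
  row.names(out) <- NULL
  out
}

#' Parse a residue score file
#'
#' Reads the 4-column plain-text score format: amino-acid change token,
#' one-letter residue code, residue number, pathogenicity score in `[0, 1]`.
#' Columns are whitespace- or tab-separated; `#` comments and blank lines are
#' ignored.
#'
#' @param path file path (ignored when `text` given).
#' @param text optional character vector of lines.
#' @return `data.frame`: `aa_change`, `res_code`, `res_num`, `score`, in file
#'   order.
#' @export
parse_score_file <- function(path, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) != 4L) {
      stop("score-file parse error at entry ", i, ": expected 4 columns",
           call. = FALSE)
    }
    score <- suppressWarnings(as.numeric(fields[4]))
    num <- suppressWarnings(as.integer(fields[3]))
    if (is.na(score) || is.na(num)) {
      stop("score-file parse error at entry ", i, call. = FALSE)
    }
    data.frame(aa_change = fields[1], res_code = toupper(fields[2]),
               res_num = num, score = score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    stop("score file holds no entries", call. = FALSE)
  }
  if (any(out$score < 0 | out$score > 1)) {
    stop("score out of range: pathogenicity scores must lie in [0, 1]",
         call. = FALSE)
  }
  dup <- out$res_num[duplicated(out$res_num)]
  if (length(dup)) {
    stop("duplicate residue number(s) in score file: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a residue score file
#'
#' @param entries `data.frame` as returned by [parse_score_file()].
#' @param path output file; when `NULL` the lines are returned.
#' @return invisibly (or visibly when `path` is `NULL`), the lines.
#' @export
write_score_file <- function(entries, path = NULL) {
  lines <- paste(entries$aa_change, entries$res_code, entries$res_num,
                 format(entries$score, trim = TRUE), sep = "\t")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Paint per-residue scores into the B-factor column
#'
#' Writes each listed residue's pathogenicity score into the B-factor field
#' (columns 61-66, `%6.2f`) of every atom of that residue; all other atoms
#' receive `default`. Original B-factors (e.g. pLDDT confidences of a
#' predicted model) are overwritten — a notice is emitted. Before writing,
#' each entry is validated against the model: the residue number must exist
#' in the selected chain and the model's residue type must match the entry's
#' one-letter code.
#'
#' @param model a `pdb_model`.
#' @param entries `data.frame` from [parse_score_file()] (`res_code`,
#'   `res_num`, `score`).
#' @param default B-factor for unlisted residues, default 0.5 (the
#'   VUS-neutral midpoint).
#' @param chain chain selector; default = first chain.
#' @param quiet suppress the overwrite notice.
#' @return the annotated `pdb_model`.
#' @export
annotate_bfactor <- function(model, entries, default = 0.5, chain = NULL,
                             quiet = FALSE) {
  stopifnot(inherits(model, "pdb_model"))
  atoms <- model$atoms
  if (is.null(chain)) chain <- atoms$chain[atoms$record == "ATOM"][1]
  sel <- atoms$record == "ATOM" & atoms$chain == chain
  if (nrow(entries)) {
    if (any(entries$score < 0 | entries$score > 1)) {
      stop("score out of range: pathogenicity scores must lie in [0, 1]",
           call. = FALSE)
    }
    model_res <- atoms$res_name[sel][match(entries$res_num,
                                           atoms$res_num[sel])]
    missing <- is.na(model_res)
    if (any(missing)) {
      stop("missing residue(s) in model: ",
           paste(entries$res_num[missing], collapse = ", "), call. = FALSE)
    }
    model_code <- unname(AA_321[model_res])
    mismatch <- is.na(model_code) | model_code != entries$res_code
    if (any(mismatch)) {
      stop("residue identity mismatch: ",
           paste0("entry ", entries$res_code[mismatch],
                  entries$res_num[mismatch], " vs model ",
                  model_res[mismatch], entries$res_num[mismatch],
                  collapse = "; "), call. = FALSE)
    }
  }
  if (!quiet) {
    message("annotate_bfactor: original B-factor values (e.g. pLDDT) ",
            "are discarded")
  }
  new_b <- rep(default, nrow(atoms))
  if (nrow(entries)) {
    hit <- match(atoms$res_num, entries$res_num)
    use <- sel & !is.na(hit)
    new_b[use] <- entries$score[hit[use]]
  }
  model$atoms$b_factor <- new_b
  field <- sprintf("%6.2f", new_b)
  lines <- model$lines
  li <- model$atoms$line
  lines[li] <- paste0(substr(lines[li], 1, 60), field,
                      substring(lines[li], 67))
  model$lines <- lines
  model
}

#' Extract per-residue pLDDT confidences
#'
#' Reads the B-factor channel as per-residue model confidence (the caller
#' asserts that the file is a predicted model whose B-factors hold pLDDT),
#' taking each residue's first-atom value, and flags residues below a
#' confidence threshold.
#'
#' @param model a `pdb_model`.
#' @param threshold confidence cutoff, default 70 (the usual "low or very
#'   low" boundary).
#' @param chain chain selector; default = first chain.
#' @return `data.frame`: `chain`, `res_num`, `res_name`, `plddt`, `low`
#'   (logical, `plddt < threshold`).
#' @export
extract_plddt <- function(model, threshold = 70, chain = NULL) {
  res <- pdb_residues(model, chain = chain)
  names(res)[names(res) == "b_factor"] <- "plddt"
  res$low <- res$plddt < threshold
  res
}
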