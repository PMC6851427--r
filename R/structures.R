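#' Structure models as tidy atom tables
#'
#' A `structure_model` wraps a per-atom tibble (one row per atom) together
#' with a model identifier and chain id. Atom rows carry the author residue
#' number and insertion code, the 3-letter residue name, the atom label,
#' Cartesian coordinates in Angstroms, occupancy, and the B-factor column
#' (`bcol`), which in refinement submissions is interpreted as the predicted
#' coordinate error in Angstroms when error estimates are in use.
#'
#' @param atoms A data frame with columns `resno`, `ins`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z`, `occ`, `bcol`.
#' @param model_id Identifier for the model (free-form; conventionally a
#'   target id, a `(target, group, model)` tag, or a role such as `"target"`,
#'   `"start"` or `"submission"`).
#' @param chain_id Single chain identifier.
#'
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = "model", chain_id = "A") {
  atoms <- tibble::as_tibble(atoms)
  required <- c("resno", "ins", "resname", "atom", "element",
                "x", "y", "z", "occ", "bcol")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  if (any(!is.na(atoms$bcol) & atoms$bcol < 0)) {
    stop("bcol (predicted coordinate error) must be non-negative")
  }
  dup <- atoms |>
    dplyr::count(.data$resno, .data$ins, .data$atom) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate atom labels within a residue: residue ",
         dup$resno[1], dup$ins[1], " atom ", dup$atom[1])
  }
  atoms <- dplyr::arrange(atoms, .data$resno, .data$ins)
  structure(
    list(model_id = model_id, chain_id = chain_id, atoms = atoms),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  nres <- nrow(dplyr::distinct(x$atoms, .data$resno, .data$ins))
  cat("<structure_model> ", format(x$model_id), "  chain ", x$chain_id,
      "  ", nres, " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Number of residues in a structure model
#' @param x A `structure_model`.
#' @return Integer residue count.
#' @export
n_residues <- function(x) {
  stopifnot(inherits(x, "structure_model"))
  nrow(dplyr::distinct(x$atoms, .data$resno, .data$ins))
}

residue_key <- function(resno, ins) {
  ins <- ifelse(is.na(ins) | ins == "", "", ins)
  paste0(resno, ins)
}

#' Read a PDB file into a structure model
#'
#' Parses the ATOM records of the first model and first chain. Alternate
#' locations are resolved to the conformer with the highest occupancy (ties
#' broken by first appearance). The B-factor column is retained in `bcol`,
#' where refinement conventions store per-residue predicted coordinate error.
#'
#' @param path Path to a PDB file.
#' @param model_id Identifier stored on the returned model; defaults to the
#'   file name without extension.
#' @return A [structure_model()].
#' @export
read_pdb <- function(path, model_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, "ATOM"))) {
    stop("no ATOM records in ", path)
  }
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  # first chain only (single-chain monomer evaluation)
  at <- at[at$chain %in% at$chain[1] | is.na(at$chain), , drop = FALSE]
  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  # resolve altlocs: keep highest occupancy, first encountered on ties
  at$occ <- ifelse(is.na(at$o), 1, at$o)
  at$.idx <- seq_len(nrow(at))
  at <- at[order(at$resno, at$ins, at$elety, -at$occ, at$.idx), , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$ins, at$elety)), , drop = FALSE]
  at <- at[order(at$.idx), , drop = FALSE]
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- substr(gsub("[0-9]", "", at$elety[is.na(elem) | elem == ""]), 1, 1)
  atoms <- tibble::tibble(
    resno = as.integer(at$resno),
    ins = at$ins,
    resname = at$resid,
    atom = at$elety,
    element = elem,
    x = at$x, y = at$y, z = at$z,
    occ = at$occ,
    bcol = ifelse(is.na(at$b), 0, at$b)
  )
  if (any(atoms$bcol < 0)) atoms$bcol[atoms$bcol < 0] <- 0
  chain <- at$chain[1]
  if (is.na(chain) || chain == "") chain <- "A"
  if (is.null(model_id)) model_id <- sub("\\.[^.]*$", "", basename(path))
  structure_model(atoms, model_id = model_id, chain_id = chain)
}

#' Write a structure model to a PDB file
#'
#' @param x A [structure_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "structure_model"))
  a <- x$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = a$resno, resid = a$resname, elety = a$atom,
    chain = rep(x$chain_id, nrow(a)),
    insert = ifelse(a$ins == "", NA, a$ins),
    o = a$occ, b = a$bcol, elesy = a$element
  )
  invisible(path)
}

#' Parse a residue-range specification
#'
#' Ranges are comma-separated `"lo-hi"` intervals or single residue numbers,
#' 1-based and inclusive, as used in refinement target definitions (e.g.
#' `"43-95, 106-181"`). Both ASCII and Unicode hyphens/dashes are accepted,
#' since published target tables often carry typographic hyphens.
#'
#' @param text Range specification string.
#' @return A `residue_ranges` tibble with columns `lo`, `hi`, sorted and
#'   non-overlapping.
#' @export
parse_residue_ranges <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  txt <- gsub("[‐‑‒–—−]", "-", text)
  tokens <- trimws(strsplit(txt, ",", fixed = TRUE)[[1]])
  tokens <- tokens[tokens != ""]
  if (length(tokens) == 0) stop("empty residue range specification")
  parse_one <- function(tok) {
    if (grepl("^[0-9]+$", tok)) {
      v <- as.integer(tok)
      return(c(v, v))
    }
    m <- regmatches(tok, regexec("^([0-9]+)\\s*-\\s*([0-9]+)$", tok))[[1]]
    if (length(m) != 3) stop("cannot parse residue range token: '", tok, "'")
    lo <- as.integer(m[2]); hi <- as.integer(m[3])
    if (lo > hi) stop("inverted residue range: ", lo, " > ", hi)
    c(lo, hi)
  }
  iv <- unname(t(vapply(tokens, parse_one, integer(2))))
  ord <- order(iv[, 1])
  iv <- iv[ord, , drop = FALSE]
  if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
    stop("overlapping residue ranges")
  }
  out <- tibble::tibble(lo = iv[, 1], hi = iv[, 2])
  class(out) <- c("residue_ranges", class(out))
  out
}

#' Count residues covered by a range specification
#'
#' @param spec A `residue_ranges` tibble from [parse_residue_ranges()], or a
#'   specification string.
#' @return Integer total residue count, `sum(hi - lo + 1)`.
#' @export
count_residues <- function(spec) {
  if (is.character(spec)) spec <- parse_residue_ranges(spec)
  sum(spec$hi - spec$lo + 1L)
}

in_ranges <- function(resno, spec) {
  if (is.null(spec)) return(rep(TRUE, length(resno)))
  out <- rep(FALSE, length(resno))
  for (i in seq_len(nrow(spec))) {
    out <- out | (resno >= spec$lo[i] & resno <= spec$hi[i])
  }
  out
}

#' Pair model and target residues by author residue number
#'
#' Refinement models share the target's residue numbering, so pairing is
#' strictly sequence-dependent: residues are paired when their
#' `(number, insertion code)` keys match, optionally restricted to an
#' evaluated residue range. No alignment search is performed.
#'
#' @param model,target `structure_model` objects.
#' @param spec Optional `residue_ranges` restriction (or specification
#'   string); only residues whose number falls in the ranges are paired.
#' @return An `alignment_map` tibble with columns `resno`, `ins`, and
#'   `has_ca` (whether both partners contain a CA atom, required for
#'   Ca-based metrics). The paired-residue count is `nrow()`.
#' @export
pair_by_residue_number <- function(model, target, spec = NULL) {
  stopifnot(inherits(model, "structure_model"), inherits(target, "structure_model"))
  if (is.character(spec)) spec <- parse_residue_ranges(spec)
  mres <- model$atoms |>
    dplyr::group_by(.data$resno, .data$ins) |>
    dplyr::summarise(ca_m = any(.data$atom == "CA"), .groups = "drop")
  tres <- target$atoms |>
    dplyr::group_by(.data$resno, .data$ins) |>
    dplyr::summarise(ca_t = any(.data$atom == "CA"), .groups = "drop")
  paired <- dplyr::inner_join(mres, tres, by = c("resno", "ins"))
  paired <- paired[in_ranges(paired$resno, spec), , drop = FALSE]
  if (nrow(paired) == 0) stop("zero paired residues between model and target")
  out <- tibble::tibble(
    resno = paired$resno, ins = paired$ins,
    has_ca = paired$ca_m & paired$ca_t
  )
  out <- dplyr::arrange(out, .data$resno, .data$ins)
  class(out) <- c("alignment_map", class(out))
  out
}

#' Read a refinement target-definition table
#'
#' Reads a tab- or comma-delimited table with columns `target_id`,
#' `residues_included`, `nres`, `category`, `start_model`, `start_gdt_ha`
#' (the layout in which refinement rounds publish their target lists). The
#' packaged CASP13 refinement table ships as
#' `system.file("extdata", "casp13_refinement_targets.tsv", package = "refinemetrics")`.
#'
#' @param path Path to the delimited file.
#' @return A tibble of target records; `nres` is validated against the
#'   parsed residue ranges.
#' @export
read_target_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           trim_ws = TRUE)
  required <- c("target_id", "residues_included", "nres", "category",
                "start_model", "start_gdt_ha")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("target table lacks columns: ", paste(missing, collapse = ", "))
  }
  tab$category <- gsub("[‐‑‒–—−]", "-", tab$category)
  tab$nres <- as.integer(tab$nres)
  counted <- vapply(tab$residues_included, count_residues, integer(1))
  bad <- which(counted != tab$nres)
  if (length(bad) > 0) {
    stop("nres does not match residue ranges for: ",
         paste(tab$target_id[bad], collapse = ", "))
  }
  tibble::as_tibble(tab)
}

#' Descriptive statistics of a refinement target table
#'
#' Summarises starting-model difficulty (GDT_HA of the start models), target
#' sizes, and category composition, the way refinement assessments describe
#' their target sets. Mean and standard deviation are reported to one
#' decimal; the SD is the sample standard deviation (n - 1 denominator).
#'
#' @param records A tibble of target records as returned by
#'   [read_target_table()] (needs `start_gdt_ha`, `nres`, `category`).
#' @return A `target_table_stats` list with components `n_targets`,
#'   `start_gdt_ha` (min, max, mean, median, sd), `nres` (min, max) and
#'   `category_counts` (tibble of category, n).
#' @export
target_table_stats <- function(records) {
  if (is.null(records) || nrow(records) < 2) {
    stop("need at least two target records")
  }
  g <- records$start_gdt_ha
  out <- list(
    n_targets = nrow(records),
    start_gdt_ha = list(
      min = min(g), max = max(g),
      mean = round(mean(g), 1),
      median = stats::median(g),
      sd = round(stats::sd(g), 1)
    ),
    nres = list(min = min(records$nres), max = max(records$nres)),
    category_counts = records |>
      dplyr::count(.data$category, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n))
  )
  class(out) <- "target_table_stats"
  out
}

#' @export
print.target_table_stats <- function(x, ...) {
  cat("Refinement target set:", x$n_targets, "targets\n")
  s <- x$start_gdt_ha
  cat(sprintf("  start GDT_HA: %g-%g (mean %.1f, median %g, SD %.1f)\n",
              s$min, s$max, s$mean, s$median, s$sd))
  cat(sprintf("  residues per target: %d-%d\n", x$nres$min, x$nres$max))
  cat("  categories:",
      paste(sprintf("%s %d", x$category_counts$category, x$category_counts$n),
            collapse = ", "), "\n")
  invisible(x)
}
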