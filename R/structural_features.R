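# Structure-derived features: lightweight PDB parsing, distance of each
# residue's C-alpha to the active-site residue (min over its atoms) and to
# the dimer partner chain, amino-acid property deltas, and ingestion of a
# per-substitution feature table (ddG, conservation, depth, ... are
# predictions from external tools and are ingested, never recomputed).

#' Parse ATOM records of a PDB file
#'
#' Fixed-width parse of `ATOM` records (first MODEL only). HETATM records
#' and waters are excluded. For alternate locations the highest-occupancy
#' conformer is kept (ties: first record). Residues lacking a C-alpha are
#' reported in the `missing_ca` attribute, not fatal. Insertion-coded and
#' nonstandard residues are skipped with a count.
#'
#' @param path PDB file path.
#' @return object of class `pdb_structure`: data.frame `atoms` with columns
#'   `chain`, `resseq`, `resname`, `atom`, `x`, `y`, `z`, `occupancy`.
#' @export
parse_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1L)]
  at <- lines[startsWith(lines, "ATOM  ")]
  if (length(at) == 0) stop("no ATOM records found in ", path, call. = FALSE)
  fw <- function(s, a, b) trimws(substr(s, a, b))
  df <- data.frame(
    atom = fw(at, 13, 16),
    altloc = substr(at, 17, 17),
    resname = fw(at, 18, 20),
    chain = substr(at, 22, 22),
    resseq = suppressWarnings(as.integer(fw(at, 23, 26))),
    icode = substr(at, 27, 27),
    x = as.numeric(fw(at, 31, 38)),
    y = as.numeric(fw(at, 39, 46)),
    z = as.numeric(fw(at, 47, 54)),
    occupancy = suppressWarnings(as.numeric(fw(at, 55, 60))),
    stringsAsFactors = FALSE)
  df$occupancy[is.na(df$occupancy)] <- 1
  n_icode <- sum(df$icode != " ")
  df <- df[df$icode == " ", , drop = FALSE]
  aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
           "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
  n_nonstd <- sum(!(df$resname %in% aa3))
  df <- df[df$resname %in% aa3, , drop = FALSE]
  if (nrow(df) == 0) stop("no standard-residue ATOM records in ", path, call. = FALSE)
  # altLoc: keep highest occupancy per (chain, resseq, atom)
  keykey <- paste(df$chain, df$resseq, df$atom, sep = "|")
  ord <- order(keykey, -df$occupancy)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$chain, df$resseq, df$atom, sep = "|")), , drop = FALSE]
  df <- df[order(df$chain, df$resseq), , drop = FALSE]
  rownames(df) <- NULL
  res_key <- unique(paste(df$chain, df$resseq, sep = "|"))
  ca_key <- paste(df$chain, df$resseq, sep = "|")[df$atom == "CA"]
  missing_ca <- setdiff(res_key, ca_key)
  if (!all(is.finite(c(df$x, df$y, df$z)))) stop("non-finite coordinates", call. = FALSE)
  structure(list(atoms = df[, c("chain", "resseq", "resname", "atom",
                                "x", "y", "z", "occupancy")],
                 missing_ca = missing_ca,
                 skipped = c(insertion_code = n_icode, nonstandard = n_nonstd)),
            class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("pdb_structure: %d atoms, %d chain(s) [%s], %d residues\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              paste(unique(x$atoms$chain), collapse = ","),
              length(unique(paste(x$atoms$chain, x$atoms$resseq)))))
  invisible(x)
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

#' Distance of each residue's C-alpha to the active-site residue
#'
#' For each target residue, the minimum over all atoms of the active-site
#' residue of the Euclidean distance to the target's C-alpha (using the
#' C-alpha on the query side maximizes sensitivity near the site).
#'
#' @param model a [parse_structure()] result.
#' @param active_resseq active-site residue number (default 147, the
#'   catalytic aspartate).
#' @param chain chain holding the active residue and the targets (default:
#'   first chain).
#' @return named numeric vector, names = residue numbers with a C-alpha.
#' @export
distance_to_active_site <- function(model, active_resseq = 147L, chain = NULL) {
  stopifnot(inherits(model, "pdb_structure"))
  atoms <- model$atoms
  if (is.null(chain)) chain <- atoms$chain[1]
  act <- atoms[atoms$chain == chain & atoms$resseq == active_resseq, , drop = FALSE]
  if (nrow(act) == 0) {
    stop("active-site residue ", active_resseq, " absent from chain ", chain, call. = FALSE)
  }
  cas <- atoms[atoms$chain == chain & atoms$atom == "CA", , drop = FALSE]
  am <- as.matrix(act[, c("x", "y", "z")])
  out <- vapply(seq_len(nrow(cas)), function(i) {
    p <- as.numeric(cas[i, c("x", "y", "z")])
    min(sqrt(rowSums((am - matrix(p, nrow(am), 3, byrow = TRUE))^2)))
  }, numeric(1))
  names(out) <- cas$resseq
  out
}

#' Distance of each residue to the dimer interface
#'
#' Per residue of `chain_a` (with a C-alpha): the minimum Euclidean distance
#' from its C-alpha to any atom of `chain_b`.
#'
#' @param model a [parse_structure()] result with >= 2 chains.
#' @param chain_a,chain_b chain identifiers (default: first two chains).
#' @return named numeric vector, names = residue numbers of `chain_a`.
#' @export
distance_to_interface <- function(model, chain_a = NULL, chain_b = NULL) {
  stopifnot(inherits(model, "pdb_structure"))
  atoms <- model$atoms
  chains <- unique(atoms$chain)
  if (length(chains) < 2) stop("interface distance requires >= 2 chains", call. = FALSE)
  if (is.null(chain_a)) chain_a <- chains[1]
  if (is.null(chain_b)) chain_b <- setdiff(chains, chain_a)[1]
  cas <- atoms[atoms$chain == chain_a & atoms$atom == "CA", , drop = FALSE]
  bm <- as.matrix(atoms[atoms$chain == chain_b, c("x", "y", "z")])
  out <- vapply(seq_len(nrow(cas)), function(i) {
    p <- as.numeric(cas[i, c("x", "y", "z")])
    min(sqrt(rowSums((bm - matrix(p, nrow(bm), 3, byrow = TRUE))^2)))
  }, numeric(1))
  names(out) <- cas$resseq
  out
}

#' Amino-acid property table bundled with the package
#'
#' Octanol/water logP and isoelectric point (pI) of the 20 free amino acids
#' (reference literature values).
#'
#' @return data.frame with columns `aa`, `logP`, `pI`.
#' @export
aa_properties <- function() {
  path <- system.file("extdata", "aa_properties.tsv", package = "envdms")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Property deltas of a substitution
#'
#' `delta = prop(mut) - prop(wt)` for logP and pI from the bundled table.
#'
#' @param wt_aa,mut_aa single-letter amino acids (vectors accepted).
#' @param table property table (default: bundled).
#' @return data.frame with columns `dlogP`, `dpI`.
#' @export
property_deltas <- function(wt_aa, mut_aa, table = aa_properties()) {
  iw <- match(wt_aa, table$aa)
  im <- match(mut_aa, table$aa)
  if (anyNA(iw) || anyNA(im)) {
    bad <- unique(c(wt_aa[is.na(iw)], mut_aa[is.na(im)]))
    stop("nonstandard amino acid(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  data.frame(dlogP = table$logP[im] - table$logP[iw],
             dpI = table$pI[im] - table$pI[iw])
}

feature_cols <- c("ddG", "dist_active", "dist_interface", "depth",
                  "conservation", "flexibility", "dlogP", "dSASA", "dpI")
positional_feature_cols <- c("dist_active", "dist_interface", "depth",
                             "conservation", "flexibility")

#' Load a per-substitution feature table and join it to the catalogue
#'
#' The TSV must carry columns `position`, `wt`, `mut` plus any of the
#' feature columns (`ddG`, `dist_active`, `dist_interface`, `depth`,
#' `conservation`, `flexibility`, `dlogP`, `dSASA`, `dpI`). Validates that
#' keys are unique, that positional features are constant across
#' substitutions at the same position, and that coverage of the catalogue's
#' non-synonymous substitutions is at least `min_coverage`. ddG follows the
#' destabilizing-positive sign convention.
#'
#' @param path TSV path.
#' @param catalogue mutant catalogue (amino-acid level: needs `position`,
#'   `wt_aa`, `mut_aa`, `synonymous`); `NULL` skips the join/coverage check.
#' @param min_coverage minimum covered fraction (default 0.9).
#' @return `feature_table` data.frame (`position`, `wt`, `mut`, features),
#'   attribute `coverage`.
#' @export
load_feature_table <- function(path, catalogue = NULL, min_coverage = 0.9) {
  ftab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "wt", "mut")
  if (!all(need %in% names(ftab))) {
    stop("feature table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  key <- paste(ftab$position, ftab$wt, ftab$mut)
  if (anyDuplicated(key)) stop("duplicate substitution keys in feature table", call. = FALSE)
  for (cc in intersect(positional_feature_cols, names(ftab))) {
    rng <- tapply(ftab[[cc]], ftab$position, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) 0 else diff(range(v))
    })
    if (any(rng > 1e-9)) {
      stop("positional feature '", cc, "' differs between substitutions at position(s) ",
           paste(names(rng)[rng > 1e-9], collapse = ", "), call. = FALSE)
    }
  }
  coverage <- NA_real_
  if (!is.null(catalogue)) {
    ns <- catalogue[!catalogue$synonymous & !(catalogue$stop %in% TRUE), , drop = FALSE]
    lib_key <- unique(paste(ns$position, ns$wt_aa, ns$mut_aa))
    coverage <- mean(lib_key %in% key)
    if (coverage < min_coverage) {
      stop(sprintf("feature table covers %.1f%% of library substitutions (< %.0f%%)",
                   100 * coverage, 100 * min_coverage), call. = FALSE)
    }
  }
  structure(ftab, coverage = coverage, class = c("feature_table", "data.frame"))
}

#' Write a feature table TSV
#'
#' @param ftab a `feature_table` (or compatible data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ftab, path) {
  utils::write.table(as.data.frame(ftab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
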