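#' Average amino-acid residue masses
#'
#' Monoisotope-free average masses of the 20 standard amino-acid residues
#' (i.e. the free amino acid minus one water), in unified atomic mass units.
#' Unknown residue names fall back to the mean of this table with a warning.
#'
#' @format Named numeric vector of length 20 (three-letter residue codes).
#' @keywords internal
residue_masses <- c(
  ALA =  71.0788, ARG = 156.1875, ASN = 114.1038, ASP = 115.0886,
  CYS = 103.1388, GLN = 128.1307, GLU = 129.1155, GLY =  57.0519,
  HIS = 137.1411, ILE = 113.1594, LEU = 113.1594, LYS = 128.1741,
  MET = 131.1926, PHE = 147.1766, PRO =  97.1167, SER =  87.0782,
  THR = 101.1051, TRP = 186.2132, TYR = 163.1760, VAL =  99.1326
)

#' Construct a coarse-grained structure
#'
#' One node per residue (normally its C-alpha atom), with coordinates in
#' Angstrom, per-node masses in amu and, optionally, experimental B-factors
#' in A^2.
#'
#' @param xyz numeric N x 3 matrix of node coordinates (Angstrom).
#' @param masses numeric vector of N node masses (amu), all > 0.
#' @param chain character vector of chain identifiers (recycled if length 1).
#' @param resno integer vector of residue numbers; the pair (chain, resno,
#'   insert) must be unique across nodes.
#' @param resid character vector of three-letter residue names.
#' @param insert character vector of insertion codes ("" when absent).
#' @param bfactors optional numeric vector of experimental B-factors (A^2),
#'   all > 0.
#' @param source_id free-text provenance label (e.g. a PDB code or a fixture
#'   recipe name).
#'
#' @return An object of class \code{cg_structure}: a list with elements
#'   \code{n}, \code{xyz}, \code{masses}, \code{chain}, \code{resno},
#'   \code{resid}, \code{insert}, \code{bfactors}, \code{source_id}.
#' @export
cg_structure <- function(xyz, masses, chain = "A", resno = NULL,
                         resid = "ALA", insert = "", bfactors = NULL,
                         source_id = "synthetic") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L)
    stop("'xyz' must be an N x 3 coordinate matrix")
  n <- nrow(xyz)
  if (n < 2L)
    stop("a coarse-grained structure needs at least 2 nodes")
  if (!all(is.finite(xyz)))
    stop("all coordinates must be finite")
  masses <- as.numeric(masses)
  if (length(masses) == 1L) masses <- rep(masses, n)
  if (length(masses) != n || any(!is.finite(masses)) || any(masses <= 0))
    stop("'masses' must be ", n, " finite positive values (amu)")
  if (is.null(resno)) resno <- seq_len(n)
  chain  <- rep_len(as.character(chain), n)
  resid  <- rep_len(as.character(resid), n)
  insert <- rep_len(as.character(insert), n)
  resno  <- as.integer(resno)
  key <- paste(chain, resno, insert, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (chain, residue number) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (!is.null(bfactors)) {
    bfactors <- as.numeric(bfactors)
    if (length(bfactors) != n || any(!is.finite(bfactors)) || any(bfactors <= 0))
      stop("'bfactors' must be ", n, " finite positive values (A^2)")
  }
  structure(
    list(n = n, xyz = unname(xyz), masses = masses, chain = chain,
         resno = resno, resid = resid, insert = insert,
         bfactors = bfactors, source_id = source_id),
    class = "cg_structure")
}

#' @export
print.cg_structure <- function(x, ...) {
  cat("Coarse-grained structure:", x$source_id, "\n")
  cat("  nodes:", x$n, " chains:", paste(unique(x$chain), collapse = ","), "\n")
  cat("  total mass:", round(sum(x$masses), 1), "amu\n")
  cat("  experimental B-factors:", if (is.null(x$bfactors)) "absent" else "present", "\n")
  invisible(x)
}

#' Read a PDB file into a coarse-grained C-alpha structure
#'
#' Keeps one node per residue at its C-alpha position. HETATM records and
#' waters are excluded; for alternate-location conformers the
#' highest-occupancy one is kept (ties: first listed). Residue masses come
#' from \code{\link{residue_masses}}; the C-alpha B-factor column is stored
#' as the experimental B-factors. Residues without a C-alpha are skipped
#' with a warning.
#'
#' @param pdb_source path to a PDB file (anything \code{bio3d::read.pdb}
#'   accepts).
#' @param chains optional character vector of chain ids to keep.
#'
#' @return A \code{\link{cg_structure}}.
#' @export
read_structure <- function(pdb_source, chains = NULL) {
  pdb <- bio3d::read.pdb(pdb_source, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("no C-alpha atoms found in '", pdb_source, "'")
  ca$insert[is.na(ca$insert)] <- ""
  ca$o[is.na(ca$o)] <- 1
  key <- paste(ca$chain, ca$resno, ca$insert, sep = "|")
  ## altloc resolution: highest occupancy wins, first-listed breaks ties
  keep <- unlist(lapply(split(seq_len(nrow(ca)), key), function(idx) {
    idx[which.max(ca$o[idx])]
  }), use.names = FALSE)
  ca <- ca[sort(keep), , drop = FALSE]
  if (nrow(ca) < 2L)
    stop("fewer than 2 C-alpha nodes after selection")

  n_res_with_ca <- nrow(ca)
  all_keys <- unique(paste(at$chain, at$resno, at$insert, sep = "|"))
  ## count residues lacking a C-alpha (insert codes NA -> "")
  all_keys2 <- unique(paste(at$chain, at$resno,
                            ifelse(is.na(at$insert), "", at$insert), sep = "|"))
  n_skipped <- length(all_keys2) - n_res_with_ca
  if (n_skipped > 0)
    warning(n_skipped, " residue(s) without a C-alpha atom skipped")

  m <- residue_masses[ca$resid]
  if (anyNA(m)) {
    unknown <- unique(ca$resid[is.na(m)])
    warning("unknown residue name(s) ", paste(unknown, collapse = ", "),
            ": using the mean residue mass")
    m[is.na(m)] <- mean(residue_masses)
  }
  b <- ca$b
  if (any(!is.finite(b)) || any(b <= 0)) b <- NULL

  cg_structure(xyz = cbind(ca$x, ca$y, ca$z), masses = unname(m),
               chain = ca$chain, resno = ca$resno, resid = ca$resid,
               insert = ca$insert, bfactors = b,
               source_id = basename(as.character(pdb_source)))
}
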