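#' Pedigree structure for a set of independent families
#'
#' Builds a validated pedigree set from per-individual records.  Parent
#' links must stay within the family; "missing" parents (founders) are
#' coded `NA` or `"0"`.  Cyclic parent links and references to
#' non-existent individuals are structural errors.
#'
#' @param fid family identifier (character or coercible).
#' @param iid individual identifier, unique within a family.
#' @param father,mother parent identifiers; `NA` or `"0"` for unknown.
#' @param sex optional; 1 = male, 2 = female, anything else unknown.
#' @return an object of class `pedigree_set`: a list of family records,
#'   each with `fid`, `id`, `father`, `mother`, `sex`, `founder`, and the
#'   members topologically ordered (parents before children).
#' @export
pedigree_set <- function(fid, iid, father = NA, mother = NA, sex = NA) {
  n <- length(iid)
  fid <- as.character(rep_len(fid, n))
  iid <- as.character(iid)
  father <- as.character(rep_len(father, n))
  mother <- as.character(rep_len(mother, n))
  sex <- rep_len(as.integer(ifelse(is.na(sex), 0L, sex)), n)
  father[father %in% c("0", "", "NA")] <- NA
  mother[mother %in% c("0", "", "NA")] <- NA
  if (anyNA(iid) || any(iid == "")) stop("individual ids must be non-missing")

  fams <- split(seq_len(n), fid)
  families <- lapply(fams, function(idx) {
    ids <- iid[idx]
    if (anyDuplicated(ids)) stop("duplicated individual id in family ", fid[idx[1]])
    fa <- father[idx]; mo <- mother[idx]
    bad <- setdiff(c(fa[!is.na(fa)], mo[!is.na(mo)]), ids)
    if (length(bad))
      stop("family ", fid[idx[1]], ": parent id(s) not in family: ",
           paste(bad, collapse = ", "))
    ord <- toposort_pedigree(ids, fa, mo, fid[idx[1]])
    list(fid = fid[idx[1]],
         id = ids[ord], father = fa[ord], mother = mo[ord],
         sex = sex[idx][ord],
         founder = is.na(fa[ord]) & is.na(mo[ord]))
  })
  # keep input family order
  families <- families[unique(fid)]
  structure(list(families = families), class = "pedigree_set")
}

# Kahn-style topological sort; children after parents, cycles rejected.
toposort_pedigree <- function(ids, father, mother, fid) {
  n <- length(ids)
  fa <- match(father, ids)
  mo <- match(mother, ids)
  placed <- logical(n)
  ord <- integer(0)
  fa1 <- ifelse(is.na(fa), 1L, fa)
  mo1 <- ifelse(is.na(mo), 1L, mo)
  repeat {
    ready <- which(!placed &
                     (is.na(fa) | placed[fa1]) &
                     (is.na(mo) | placed[mo1]))
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) != n)
    stop("family ", fid, ": cycle in parent links")
  ord
}

#' @export
print.pedigree_set <- function(x, ...) {
  sizes <- vapply(x$families, function(f) length(f$id), integer(1))
  cat("pedigree_set:", length(x$families), "families,",
      sum(sizes), "individuals (sizes ",
      paste(range(sizes), collapse = "-"), ")\n", sep = " ")
  invisible(x)
}

#' Read a PLINK-style FAM file
#'
#' Whitespace-delimited, six columns (FID, IID, PAT, MAT, SEX, PHENO);
#' `0` codes a missing parent; the phenotype column is ignored.
#'
#' @param path file path.
#' @return a `pedigree_set`.
#' @export
read_fam <- function(path) {
  d <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(d) < 4) stop("FAM file must have at least 4 columns")
  sex <- if (ncol(d) >= 5) suppressWarnings(as.integer(d[[5]])) else NA
  pedigree_set(d[[1]], d[[2]], d[[3]], d[[4]], sex)
}

#' Per-family genetic-correlation matrices from pedigree structure
#'
#' The genetic correlation between two non-inbred relatives is twice
#' their kinship coefficient.  Kinship is computed by the standard
#' recursion in topological order: founders have self-kinship 1/2 and
#' kinship 0 to other founders; a child `c` of parents `(f, m)` has
#' `phi(c, j) = (phi(f, j) + phi(m, j)) / 2` for previously placed `j`
#' and `phi(c, c) = (1 + phi(f, m)) / 2`.  A missing parent contributes
#' kinship 0.  Inbred pedigrees are handled (the diagonal may exceed 1).
#'
#' @param ped a `pedigree_set`.
#' @return named list of per-family symmetric matrices `Omega_i`
#'   (dimnames = individual ids, in topological order).
#' @export
genetic_correlation_from_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree_set"))
  lapply(ped$families, function(fam) {
    n <- length(fam$id)
    phi <- matrix(0, n, n, dimnames = list(fam$id, fam$id))
    fa <- match(fam$father, fam$id)
    mo <- match(fam$mother, fam$id)
    for (c in seq_len(n)) {
      f <- fa[c]; m <- mo[c]
      if (is.na(f) && is.na(m)) {
        phi[c, c] <- 0.5
      } else {
        prev <- seq_len(c - 1L)
        kf <- if (is.na(f)) rep(0, c - 1L) else phi[f, prev]
        km <- if (is.na(m)) rep(0, c - 1L) else phi[m, prev]
        phi[c, prev] <- phi[prev, c] <- (kf + km) / 2
        phifm <- if (is.na(f) || is.na(m)) 0 else phi[f, m]
        phi[c, c] <- (1 + phifm) / 2
      }
    }
    2 * phi
  })
}

#' Genomic estimate of the genetic-correlation matrix
#'
#' Estimates relatedness directly from genotype dosages when pedigree
#' structure is unknown: the average over variants of the products of
#' allele-frequency-standardized dosages,
#' `Omega[j, j'] = (1/p) sum_l (g_jl - 2 m_l)(g_j'l - 2 m_l) / (2 m_l (1 - m_l))`,
#' with the diagonal computed by the same formula.
#'
#' @param G numeric matrix, individuals x variants, dosages in `[0, 2]`.
#' @param m allele-frequency vector of length `ncol(G)`, strictly inside
#'   `(0, 1)` — monomorphic variants must be filtered upstream.
#' @return symmetric matrix, individuals x individuals.
#' @export
genetic_correlation_genomic <- function(G, m) {
  G <- as.matrix(G)
  if (length(m) != ncol(G)) stop("'m' must have one entry per variant")
  if (any(m <= 0 | m >= 1)) stop("monomorphic variant (m in {0,1}); filter upstream")
  Z <- sweep(G, 2, 2 * m, "-")
  Z <- sweep(Z, 2, sqrt(2 * m * (1 - m)), "/")
  tcrossprod(Z) / ncol(G)
}
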