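#' Configuration for simulation experiments
#'
#' Collects the knobs of the type-I-error and power harnesses.  The
#' default profile is desk-scale: 300 nuclear families split 170/130
#' between the two subpopulation pools (preserving the 4:3 ratio of the
#' full-scale 800/600 design), 2,000 replicates, and nominal levels 0.05
#' and 0.01.  The full-scale profile (1,400 families, 50,000 replicates)
#' is available by overriding `n_fam` and `n_rep` but is a cluster-scale
#' computation.
#'
#' @param scenario `"null"`, `"hom"` (homogeneous effects on all traits)
#'   or `"het"` (effects on trait 1 only).
#' @param trait_kind `"continuous"` or `"binary"`.
#' @param n_fam families per pool, `c(nEUR, nAA)`.
#' @param n_rep number of replicates (>= 100 for any reported rate).
#' @param levels nominal significance levels.
#' @param weight_specs named list of beta-shape pairs.
#' @param structures named list of `c(corstr_n, corstr_K)` pairs.
#' @param p_variants,n_hap region size and pool size per replicate.
#' @param pos_frac fraction of causal variants with positive (risk) sign.
#' @param seed master seed; replicate `r` runs under `seed + r` so any
#'   replicate is reproducible in isolation.
#' @param maf_min MAF filter applied before testing.
#' @param verbose print progress every 100 replicates.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(scenario = "null", trait_kind = "continuous",
                              n_fam = c(170L, 130L), n_rep = 2000L,
                              levels = c(0.05, 0.01),
                              weight_specs = list(unweighted = c(1, 1),
                                                  weighted = c(1, 25)),
                              structures = list(
                                EE = c("exchangeable", "exchangeable"),
                                UU = c("unstructured", "unstructured")),
                              p_variants = 30L, n_hap = 2000L,
                              pos_frac = 1, seed = 1L, maf_min = 0,
                              verbose = FALSE) {
  if (n_rep < 100L) stop("use at least 100 replicates for any reported rate")
  if (!all(levels %in% c(0.05, 0.01, 0.001, 0.0001)))
    stop("levels must be a subset of {0.05, 0.01, 0.001, 0.0001}")
  structure(list(scenario = scenario, trait_kind = trait_kind,
                 n_fam = n_fam, n_rep = as.integer(n_rep), levels = levels,
                 weight_specs = weight_specs, structures = structures,
                 p_variants = as.integer(p_variants),
                 n_hap = as.integer(n_hap), pos_frac = pos_frac,
                 seed = as.integer(seed), maf_min = maf_min,
                 verbose = isTRUE(verbose)),
            class = "experiment_config")
}

famkat_methods <- c("HoK", "HeK", "BT", "HoO", "HeO")

# Per-replicate seed: spread master seeds far apart so different masters
# give disjoint replicate streams (seed + r would overlap heavily).
replicate_seed <- function(master, r) {
  as.integer((as.numeric(master) * 1000003 + r) %% 2147483647)
}

#' Replicate-level p-values of the full test battery
#'
#' Workhorse shared by [type1_experiment()] and [power_experiment()]:
#' for each replicate, generates a fresh haplotype-pool pair and study
#' data under the configured scenario, fits the joint-GEE null model for
#' every working-structure pair, and records the five tests' p-values
#' for every weight spec.  Replicates whose fit fails are recorded as
#' `NA` and counted.
#'
#' @param cfg an [experiment_config()].
#' @return list with `p` (array replicate x structure x weight x method),
#'   `stat` (same shape, statistics), `failures` (count), `cfg`.
#' @export
replicate_pvalues <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  meth <- famkat_methods
  ns <- names(cfg$structures); nw <- names(cfg$weight_specs)
  P <- array(NA_real_, c(cfg$n_rep, length(ns), length(nw), length(meth)),
             dimnames = list(NULL, ns, nw, meth))
  Stat <- P
  failures <- 0L
  N <- sum(cfg$n_fam)
  Omega <- trio_omega(N)
  for (r in seq_len(cfg$n_rep)) {
    set.seed(replicate_seed(cfg$seed, r))
    ok <- tryCatch({
      pools <- make_pools(cfg$p_variants, cfg$n_hap)
      data <- simulate_study(pools, cfg$n_fam, cfg$trait_kind, cfg$scenario,
                             pos_frac = cfg$pos_frac)
      gs0 <- genotype_summary(data$G, founder = data$founder,
                              maf_min = cfg$maf_min)
      for (s in seq_along(ns)) {
        st <- cfg$structures[[s]]
        fit <- jgee_null(data, corstr_n = st[1], corstr_K = st[2])
        sc <- score_components(fit, Omega,
                               data$G[, gs0$keep, drop = FALSE])
        for (wi in seq_along(nw)) {
          res <- run_all_tests(fit, Omega, weights = cfg$weight_specs[[wi]],
                               gs = gs0, sc = sc)
          for (mm in meth) {
            P[r, s, wi, mm] <- res[[mm]]$p
            Stat[r, s, wi, mm] <- res[[mm]]$statistic
          }
        }
      }
      TRUE
    }, error = function(e) FALSE)
    if (!ok) failures <- failures + 1L
    if (cfg$verbose && r %% 100L == 0L)
      message("replicate ", r, "/", cfg$n_rep)
  }
  list(p = P, stat = Stat, failures = failures, cfg = cfg)
}

rate_table <- function(rep_out, levels) {
  P <- rep_out$p
  dn <- dimnames(P)
  out <- expand.grid(structure = dn[[2]], weight = dn[[3]],
                     method = dn[[4]], level = levels,
                     stringsAsFactors = FALSE)
  out$rate <- NA_real_; out$se <- NA_real_; out$n_used <- NA_integer_
  for (i in seq_len(nrow(out))) {
    pv <- P[, out$structure[i], out$weight[i], out$method[i]]
    pv <- pv[!is.na(pv)]
    n <- length(pv)
    rate <- mean(pv < out$level[i])
    out$rate[i] <- rate
    out$se[i] <- sqrt(rate * (1 - rate) / n)
    out$n_used[i] <- n
  }
  out
}

#' Empirical type-I-error experiment
#'
#' Runs null-scenario replicates and tabulates, for every working
#' structure, weight spec, method and nominal level, the fraction of
#' p-values below the level, with its binomial standard error.
#'
#' @param cfg an [experiment_config()] with `scenario = "null"`.
#' @return data.frame of rates with attributes `failures` and `flagged`
#'   (`TRUE` if more than 1\% of replicates failed).
#' @export
type1_experiment <- function(cfg) {
  if (cfg$scenario != "null") stop("type-I-error experiment requires scenario 'null'")
  rep_out <- replicate_pvalues(cfg)
  tab <- rate_table(rep_out, cfg$levels)
  attr(tab, "failures") <- rep_out$failures
  attr(tab, "flagged") <- rep_out$failures > 0.01 * cfg$n_rep
  attr(tab, "seed") <- cfg$seed
  tab
}

#' Empirical power experiment
#'
#' Runs alternative-scenario replicates (`"hom"` or `"het"`) and
#' tabulates empirical power, plus a pairwise ordering summary of the
#' kernel statistics and of weighted vs unweighted tests.
#'
#' @param cfg an [experiment_config()] with `scenario` `"hom"` or `"het"`.
#' @return data.frame of rates; attribute `ordering` holds the pairwise
#'   comparison table.
#' @export
power_experiment <- function(cfg) {
  if (!cfg$scenario %in% c("hom", "het"))
    stop("power experiment requires scenario 'hom' or 'het'")
  rep_out <- replicate_pvalues(cfg)
  tab <- rate_table(rep_out, cfg$levels)
  ordering <- do.call(rbind, lapply(cfg$levels, function(lv) {
    sub <- tab[tab$level == lv, ]
    g <- function(m, w, s) sub$rate[sub$method == m & sub$weight == w &
                                      sub$structure == s][1]
    s1 <- names(cfg$structures)[1]
    w1 <- names(cfg$weight_specs)[1]
    rows <- data.frame(level = lv,
                       comparison = c("HeK-vs-HoK", "weighted-vs-unweighted(HoK)"),
                       delta = c(g("HeK", w1, s1) - g("HoK", w1, s1),
                                 if (length(cfg$weight_specs) > 1)
                                   g("HoK", names(cfg$weight_specs)[2], s1) -
                                     g("HoK", w1, s1) else NA_real_))
    rows
  }))
  attr(tab, "ordering") <- ordering
  attr(tab, "failures") <- rep_out$failures
  attr(tab, "seed") <- cfg$seed
  tab
}

#' Region-based association analysis of user data
#'
#' Reads standard files (VCF genotypes, PLINK FAM pedigree, phenotype /
#' covariate TSV), assembles the per-family data, fits the joint-GEE
#' null model once, and runs the five region tests, optionally per
#' region of a BED-like table.
#'
#' @param vcf path to a VCF file (or a pre-read list from
#'   [read_vcf_dosage()]).
#' @param fam path to a FAM file.
#' @param pheno path to a phenotype TSV (`FID`, `IID`, traits,
#'   covariates).
#' @param n_traits number of trait columns.
#' @param trait_kind `"continuous"` or `"binary"`.
#' @param corstr_n,corstr_K working correlation structures.
#' @param weights beta-shape weight pair.
#' @param omega `"pedigree"` (kinship recursion on the FAM structure) or
#'   `"genomic"` (allele-frequency-standardized dosage products).
#' @param regions optional data.frame with columns `chrom`, `start`,
#'   `end` (and optionally `name`): each row is tested as a region.
#' @param maf_min MAF filter.
#' @param out optional path for a results TSV.
#' @return data.frame of results (one row per region x method).
#' @export
analyze_region <- function(vcf, fam, pheno, n_traits,
                           trait_kind = "continuous",
                           corstr_n = "exchangeable",
                           corstr_K = "exchangeable",
                           weights = c(1, 1), omega = c("pedigree", "genomic"),
                           regions = NULL, maf_min = 0, out = NULL) {
  omega <- match.arg(omega)
  ped <- read_fam(fam)
  vd <- if (is.character(vcf)) read_vcf_dosage(vcf) else vcf
  ph <- read_pheno_tsv(pheno, n_traits)

  ids_ped <- unlist(lapply(ped$families, function(f) f$id), use.names = FALSE)
  miss_g <- setdiff(ids_ped, rownames(vd$G))
  miss_p <- setdiff(ids_ped, ph$IID)
  if (length(miss_g) || length(miss_p))
    stop("sample-ID mismatch; missing from VCF: ",
         paste(miss_g, collapse = ","), "; missing from phenotypes: ",
         paste(miss_p, collapse = ","))

  K <- n_traits
  q_cols <- setdiff(names(ph), c("FID", "IID"))
  trait_cols <- q_cols[seq_len(K)]
  cov_cols <- q_cols[-seq_len(K)]
  families <- lapply(ped$families, function(f) {
    rows <- match(f$id, ph$IID)
    list(y = as.matrix(ph[rows, trait_cols, drop = FALSE]),
         x = cbind(1, as.matrix(ph[rows, cov_cols, drop = FALSE])),
         g = vd$G[f$id, , drop = FALSE],
         fid = f$fid, founder = f$founder)
  })
  data <- family_data_set(families, rep(trait_kind, K))
  data$iid <- unlist(lapply(ped$families, function(f) f$id), use.names = FALSE)

  Omega <- if (omega == "pedigree") {
    genetic_correlation_from_pedigree(ped)
  } else {
    gs0 <- genotype_summary(data$G, founder = data$founder)
    lapply(seq_along(ped$families), function(i) {
      b <- family_blocks(data, i)
      genetic_correlation_genomic(b$g[, gs0$keep, drop = FALSE], gs0$m)
    })
  }

  fit <- jgee_null(data, corstr_n = corstr_n, corstr_K = corstr_K)

  run_one <- function(cols, label) {
    gs <- genotype_summary(data$G[, cols, drop = FALSE],
                           founder = data$founder, weights = weights,
                           maf_min = maf_min)
    sc <- score_components(fit, Omega, data$G[, cols, drop = FALSE][, gs$keep,
                                                                   drop = FALSE])
    hok <- hok_test(sc, gs); hek <- hek_test(sc, gs); bt <- burden_test(sc, gs)
    res <- list(HoK = hok, HeK = hek, BT = bt,
                HoO = cauchy_omnibus(hok$p, bt$p, "HoO"),
                HeO = cauchy_omnibus(hek$p, bt$p, "HeO"))
    cbind(region = label,
          as.data.frame(structure(c(res, list(summary = gs)),
                                  class = "famkat_results")))
  }

  df <- if (is.null(regions)) {
    run_one(seq_len(ncol(data$G)), "all")
  } else {
    do.call(rbind, lapply(seq_len(nrow(regions)), function(ri) {
      sel <- which(vd$pos$chrom == as.character(regions$chrom[ri]) &
                     vd$pos$pos >= regions$start[ri] &
                     vd$pos$pos <= regions$end[ri])
      if (!length(sel)) return(NULL)
      lbl <- if ("name" %in% names(regions)) as.character(regions$name[ri])
      else paste0(regions$chrom[ri], ":", regions$start[ri], "-", regions$end[ri])
      run_one(sel, lbl)
    }))
  }
  if (!is.null(out)) write_results_tsv(df, out)
  df
}
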