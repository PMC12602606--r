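#' Toy genome for synthetic cohorts
#'
#' Builds a small all-autosome genome used to place methylation probes and
#' to define sub-telomeric and peri-centromeric windows. Defaults to six
#' 50 Mb autosomes with centromeres spanning 24-26 Mb, enough chromosomes
#' for per-chromosome region summaries while staying test-sized.
#'
#' @param n_chrom Number of autosomes (>= 2).
#' @param length_bp Chromosome length in bp (same for all chromosomes).
#' @param cen_start_bp,cen_end_bp Centromere interval (1-based, inclusive),
#'   `0 < cen_start < cen_end < length_bp`.
#' @return A `toy_genome`: data.frame with columns `chrom`, `length_bp`,
#'   `cen_start_bp`, `cen_end_bp`.
#' @export
toy_genome <- function(n_chrom = 6, length_bp = 50e6,
                       cen_start_bp = 24e6, cen_end_bp = 26e6) {
  if (n_chrom < 2) stop("need at least 2 chromosomes")
  if (!(0 < cen_start_bp && cen_start_bp < cen_end_bp && cen_end_bp < length_bp)) {
    stop("centromere interval must satisfy 0 < start < end < length")
  }
  g <- data.frame(
    chrom = paste0("chr", seq_len(n_chrom)),
    length_bp = as.numeric(length_bp),
    cen_start_bp = as.numeric(cen_start_bp),
    cen_end_bp = as.numeric(cen_end_bp),
    stringsAsFactors = FALSE
  )
  class(g) <- c("toy_genome", "data.frame")
  g
}

#' Default chromatin-state composition of the probe manifest
#'
#' Fractions loosely follow an islet regulatory annotation: promoters are a
#' minority of array probes, enhancer and lowly-methylated probes are
#' common, and a sizeable fraction sits in heterochromatin.
#' @return Named numeric vector summing to 1.
#' @export
default_state_fractions <- function() {
  c(active_promoter = 0.15, weak_promoter = 0.10, enhancer = 0.20,
    lowly_methylated = 0.15, heterochromatin = 0.25, other = 0.15)
}

#' Simulate a probe manifest on a toy genome
#'
#' Places `n_probes` uniformly at random on the genome (chromosome chosen
#' proportional to length, position uniform), assigns each a chromatin
#' state by the given fractions, and links every active- or weak-promoter
#' probe to exactly one gene id. Promoter probes are spread over a gene
#' pool of roughly half their number, so genes typically carry one to
#' three promoter probes as on real arrays.
#'
#' @param genome A [toy_genome()].
#' @param n_probes Number of probes (>= 100).
#' @param state_fractions Named fractions per chromatin state, summing to 1.
#' @param gene_ids Optional pool of gene ids for promoter links; generated
#'   as `g0001...` when `NULL`.
#' @param seed Integer seed; identical seeds give byte-identical manifests.
#' @return A `probe_manifest` data.frame: `probe_id`, `chrom`, `pos`
#'   (1-based), `state`, `gene` (`NA` outside promoters), sorted by
#'   chromosome then position.
#' @export
make_manifest <- function(genome, n_probes, state_fractions = default_state_fractions(),
                          gene_ids = NULL, seed = 1) {
  stopifnot(inherits(genome, "toy_genome"))
  if (n_probes < 100) stop("n_probes must be >= 100")
  if (abs(sum(state_fractions) - 1) > 1e-9) {
    stop("state_fractions must sum to 1 (got ", sum(state_fractions), ")")
  }
  if (is.null(names(state_fractions)) || any(!nzchar(names(state_fractions)))) {
    stop("state_fractions must be named")
  }
  with_seed(seed, {
    chrom <- sample(genome$chrom, n_probes, replace = TRUE,
                    prob = genome$length_bp / sum(genome$length_bp))
    len <- genome$length_bp[match(chrom, genome$chrom)]
    pos <- floor(stats::runif(n_probes, min = 0, max = len)) + 1
    state <- sample(names(state_fractions), n_probes, replace = TRUE,
                    prob = state_fractions)
    man <- data.frame(
      probe_id = sprintf("cg%07d", seq_len(n_probes)),
      chrom = chrom, pos = pos, state = state,
      gene = NA_character_, stringsAsFactors = FALSE
    )
    is_prom <- man$state %in% c("active_promoter", "weak_promoter")
    n_prom <- sum(is_prom)
    if (n_prom > 0) {
      if (is.null(gene_ids)) {
        gene_ids <- sprintf("g%04d", seq_len(max(1L, ceiling(n_prom / 2))))
      }
      man$gene[is_prom] <- sample(gene_ids, n_prom, replace = TRUE)
    }
    man <- man[order(match(man$chrom, genome$chrom), man$pos, man$probe_id), ]
    rownames(man) <- NULL
    class(man) <- c("probe_manifest", "data.frame")
    man
  })
}

#' Simulate an array-style methylation matrix with planted group effects
#'
#' Baseline per-probe methylation is drawn from the bimodal mixture typical
#' of array data (`Beta(0.5, 5)` unmethylated vs `Beta(5, 0.5)` methylated
#' component, equal weight). Per-sample noise is added on the logit scale
#' and transformed back, so values stay inside (0, 1) naturally. Two kinds
#' of effects are planted and recorded in a ground-truth ledger:
#'
#' * **Group-specific DMP blocks**: for every non-reference group a
#'   disjoint block of probes is shifted by `dmp_delta_beta` (beta scale)
#'   in that group's samples. Block probes get a mid-range baseline so the
#'   planted shift survives the unit interval, and are preferentially
#'   drawn from enhancer and lowly-methylated probes (weight
#'   `dmp_state_bias`), mirroring the enhancer enrichment of DMPs between
#'   alpha-like and ADM tumors.
#' * **Structural-region hypomethylation**: probes inside the
#'   sub-telomeric or peri-centromeric windows get a hypermethylated
#'   baseline (uniform 0.60-0.85, as in normal heterochromatin) and are
#'   shifted by `region_delta_beta` in every non-reference group,
#'   emulating the chromosome-end and centromere-flank hypomethylation of
#'   ADM tumors.
#'
#' The first element of `groups` is the reference ("alpha-like") group and
#' receives no planted effect.
#'
#' @param manifest A [make_manifest()] result.
#' @param genome The [toy_genome()] the manifest was placed on.
#' @param groups Named integer vector of group sizes (each >= 2); first
#'   entry is the reference group.
#' @param n_dmp Number of planted DMPs per non-reference group (scalar or
#'   one value per non-reference group). Blocks are disjoint.
#' @param dmp_delta_beta Planted beta shift per non-reference group
#'   (scalar or vector, may be negative).
#' @param region_delta_beta Signed beta shift applied to structural-region
#'   probes in non-reference groups (0 disables the effect).
#' @param tel_window_bp,cen_window_bp Window sizes defining sub-telomeric
#'   and peri-centromeric probes (see [define_structural_regions()]).
#' @param intermediate_probes Optional probe ids forced to an intermediate
#'   baseline (uniform 0.40-0.80). The bimodal mixture saturates many
#'   probes near 0 or 1; probes meant to carry usable inter-sample
#'   variation — e.g. the variably methylated promoter CpGs that
#'   expression is later coupled to — are drawn from this mid-range
#'   instead.
#' @param noise_sd Logit-scale noise standard deviation (> 0).
#' @param seed Integer seed.
#' @return A list with `beta` (probes x samples matrix) and `truth`, a
#'   ledger containing `sample_group`, `dmp_probes` (list per non-reference
#'   group), `dmp_delta_beta`, `region_probes` (sub-telomeric /
#'   peri-centromeric probe ids), `region_delta_beta`, and `baseline`
#'   (per-probe baseline beta).
#' @export
simulate_methylation <- function(manifest, genome,
                                 groups = c(alpha_like = 30, ADM = 60),
                                 n_dmp = 500, dmp_delta_beta = 0.3,
                                 region_delta_beta = -0.15,
                                 tel_window_bp = 2e6, cen_window_bp = 2e6,
                                 intermediate_probes = NULL,
                                 noise_sd = 0.15, seed = 1) {
  stopifnot(inherits(manifest, "data.frame"), inherits(genome, "toy_genome"))
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (is.null(names(groups)) || length(groups) < 2) {
    stop("groups must be a named vector with >= 2 groups")
  }
  if (any(groups < 2)) stop("every group needs >= 2 samples")
  alt_groups <- names(groups)[-1]
  n_dmp <- rep_len(n_dmp, length(alt_groups))
  dmp_delta_beta <- rep_len(dmp_delta_beta, length(alt_groups))

  region_map <- define_structural_regions(genome, manifest,
                                          tel_window_bp = tel_window_bp,
                                          cen_window_bp = cen_window_bp)
  region_probes <- split(names(region_map), region_map)

  with_seed(seed, {
    n_probe <- nrow(manifest)
    samples <- sprintf("S%03d", seq_len(sum(groups)))
    group_of <- rep(names(groups), groups)
    names(group_of) <- samples

    # bimodal array-like baseline
    comp <- stats::runif(n_probe) < 0.5
    baseline <- ifelse(comp, stats::rbeta(n_probe, 0.5, 5), stats::rbeta(n_probe, 5, 0.5))
    names(baseline) <- manifest$probe_id

    in_region <- manifest$probe_id %in% names(region_map)
    if (region_delta_beta != 0 && any(in_region)) {
      baseline[in_region] <- stats::runif(sum(in_region), 0.60, 0.85)
    }
    if (!is.null(intermediate_probes)) {
      keep <- intersect(intermediate_probes, names(baseline))
      baseline[keep] <- stats::runif(length(keep), 0.40, 0.80)
    }

    # disjoint DMP blocks, biased towards enhancer/lowly-methylated probes
    dmp_state_bias <- 4
    eligible <- manifest$probe_id[!in_region]
    w <- ifelse(manifest$state[!in_region] %in% c("enhancer", "lowly_methylated"),
                dmp_state_bias, 1)
    if (sum(n_dmp) > length(eligible)) stop("too many DMPs requested")
    picked <- sample(eligible, sum(n_dmp), prob = w)
    dmp_probes <- split(picked, rep(alt_groups, n_dmp))[alt_groups]
    names(dmp_probes) <- alt_groups
    for (i in seq_along(alt_groups)) {
      d <- dmp_delta_beta[i]
      pb <- dmp_probes[[i]]
      lo <- max(0.10, 0.10 - min(d, 0)) # baseline range keeping base and base+d in [0.10, 0.90]
      hi <- min(0.90, 0.90 - max(d, 0))
      if (lo >= hi) {
        warning("planted delta pushes baselines out of [0,1]; values will be clipped")
        lo <- 0.10; hi <- 0.90
      }
      baseline[pb] <- stats::runif(length(pb), lo, hi)
    }

    # expected beta per probe x sample, then logit-scale noise
    mu <- matrix(baseline, nrow = n_probe, ncol = length(samples),
                 dimnames = list(manifest$probe_id, samples))
    for (i in seq_along(alt_groups)) {
      in_g <- group_of == alt_groups[i]
      mu[dmp_probes[[i]], in_g] <- mu[dmp_probes[[i]], in_g] + dmp_delta_beta[i]
      if (region_delta_beta != 0) {
        mu[in_region, in_g] <- mu[in_region, in_g] + region_delta_beta
      }
    }
    clip_frac <- mean(mu < 0 | mu > 1)
    if (clip_frac > 0.5) warning("planted effects push >50% of expected values out of [0,1]")
    eps <- 1e-4
    mu <- pmin(pmax(mu, eps), 1 - eps)
    logit <- log(mu / (1 - mu))
    beta <- 1 / (1 + exp(-(logit + stats::rnorm(length(mu), sd = noise_sd))))

    truth <- list(
      sample_group = group_of,
      dmp_probes = dmp_probes,
      dmp_delta_beta = stats::setNames(dmp_delta_beta, alt_groups),
      region_probes = region_probes,
      region_delta_beta = region_delta_beta,
      baseline = baseline
    )
    list(beta = beta, truth = truth)
  })
}

#' Simulate a count matrix with planted subtype programs and
#' methylation-coupled genes
#'
#' Counts are negative binomial with gene-specific base means (log-normal,
#' median around 200) and per-sample library size factors (log-normal, sd
#' 0.2). Three planted effects are recorded in the ground truth:
#'
#' * **Subtype DE programs** (`de_genes`): per transcriptomic subtype a
#'   disjoint gene block whose log-mean is shifted by `log2fc * log(2)` in
#'   that subtype's samples (a configurable fraction of the block is
#'   down-regulated).
#' * **Shared signature block** (`signature_genes`): genes up-regulated in
#'   every subtype listed in `signature_subtypes`, emulating a
#'   metastasis-like-primary signature elevated in the hypoxia-like and
#'   immune-like subtypes.
#' * **Promoter-coupled genes** (`coupling`): for each (gene, probe,
#'   target_rho) row, the gene's log-mean gains a decreasing affine term
#'   in the standardized promoter-probe M-value, with amplitude chosen so
#'   the realized Spearman correlation between expression and M-value is
#'   close to `target_rho` (the target is converted to a Pearson scale via
#'   the bivariate-normal rank relation, then amplified against the NB
#'   log-scale noise).
#'
#' @param subtypes Named character vector sample -> transcriptomic subtype
#'   label. Samples labelled with names absent from `de_config` (e.g. the
#'   alpha-like reference) get baseline expression.
#' @param n_genes Number of genes; gene ids `g0001...` match the manifest's
#'   promoter links.
#' @param de_config Named list subtype -> list(n_genes, log2fc, frac_down).
#' @param signature_subtypes Character vector of subtypes sharing the
#'   signature block (empty disables it).
#' @param n_signature,signature_log2fc Size and effect of the signature block.
#' @param coupling Optional data.frame(gene, probe, target_rho); probes
#'   must be promoter probes of the matching gene in `manifest`.
#' @param manifest Manifest used to validate coupling (promoter states).
#' @param beta Methylation matrix covering the coupled probes and samples;
#'   required when `coupling` is non-empty.
#' @param nb_dispersion NB dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param seed Integer seed.
#' @return List with `counts` (genes x samples integer matrix) and `truth`
#'   (`de_genes`: per-subtype data.frame(gene, log2fc); `signature_genes`;
#'   `coupled_pairs`; `size_factors_true`).
#' @export
simulate_expression <- function(subtypes, n_genes = 5000,
                                de_config = default_de_config(),
                                signature_subtypes = c("ADM1", "ADM3"),
                                n_signature = 30, signature_log2fc = 1.5,
                                coupling = NULL, manifest = NULL, beta = NULL,
                                nb_dispersion = 0.05, seed = 1) {
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (is.null(names(subtypes))) stop("subtypes must be named by sample id")
  samples <- names(subtypes)
  genes <- sprintf("g%04d", seq_len(n_genes))

  if (!is.null(coupling) && nrow(coupling) > 0) {
    if (is.null(beta)) stop("beta matrix required for coupled pairs")
    if (is.null(manifest)) stop("manifest required for coupled pairs")
    m <- manifest[match(coupling$probe, manifest$probe_id), ]
    bad <- is.na(m$probe_id) | !(m$state %in% c("active_promoter", "weak_promoter")) |
      m$gene != coupling$gene
    if (any(bad)) {
      stop("coupled pairs must reference promoter probes of the matching gene: ",
           paste(coupling$probe[bad], collapse = ", "))
    }
    if (!all(coupling$probe %in% rownames(beta))) stop("coupled probes missing from beta")
    if (!all(samples %in% colnames(beta))) stop("beta must cover all samples")
    if (!all(coupling$gene %in% genes)) stop("coupled genes outside the gene universe")
  }

  with_seed(seed, {
    base_log_mu <- stats::rnorm(n_genes, mean = log(200), sd = 1.2)
    names(base_log_mu) <- genes
    if (!is.null(coupling) && nrow(coupling) > 0) {
      # promoter-regulated genes are expressed genes; a floor on their base
      # mean keeps the planted correlation realizable in counts
      base_log_mu[coupling$gene] <- pmax(base_log_mu[coupling$gene], log(100))
    }
    lib <- exp(stats::rnorm(length(samples), 0, 0.2))
    names(lib) <- samples

    # carve disjoint DE blocks and the shared signature block; a config may
    # pin explicit member genes (cfg$genes), the rest is drawn from the pool
    pinned <- unique(unlist(lapply(de_config, `[[`, "genes")))
    pool <- setdiff(genes, pinned)
    de_genes <- list()
    for (st in names(de_config)) {
      cfg <- de_config[[st]]
      pick <- cfg$genes
      n_more <- max(0L, cfg$n_genes - length(pick))
      if (n_more > 0) {
        pick <- c(pick, pool[seq_len(n_more)])
        pool <- setdiff(pool, pick)
      }
      sgn <- rep(1, length(pick))
      n_down <- round(cfg$frac_down * length(pick))
      if (n_down > 0) sgn[length(pick) - seq_len(n_down) + 1L] <- -1
      de_genes[[st]] <- data.frame(gene = pick, log2fc = sgn * cfg$log2fc,
                                   stringsAsFactors = FALSE)
    }
    signature_genes <- character(0)
    if (length(signature_subtypes) > 0 && n_signature > 0) {
      signature_genes <- pool[seq_len(n_signature)]
      pool <- setdiff(pool, signature_genes)
      for (st in signature_subtypes) {
        add <- data.frame(gene = signature_genes, log2fc = signature_log2fc,
                          stringsAsFactors = FALSE)
        de_genes[[st]] <- rbind(de_genes[[st]], add)
      }
    }

    log_mu <- matrix(base_log_mu, nrow = n_genes, ncol = length(samples),
                     dimnames = list(genes, samples))
    for (st in names(de_genes)) {
      in_st <- subtypes == st
      if (!any(in_st)) next
      tab <- de_genes[[st]]
      log_mu[tab$gene, in_st] <- log_mu[tab$gene, in_st] + tab$log2fc * log(2)
    }

    coupled_pairs <- NULL
    if (!is.null(coupling) && nrow(coupling) > 0) {
      coupled_pairs <- coupling
      mv <- beta_to_m(beta[coupling$probe, samples, drop = FALSE])
      for (i in seq_len(nrow(coupling))) {
        g <- coupling$gene[i]
        z <- scale(mv[i, ])[, 1]
        if (!all(is.finite(z))) z[] <- 0 # constant probe: nothing to couple to
        mu_bar <- mean(exp(log_mu[g, ]))
        sigma <- sqrt(nb_dispersion + 1 / mu_bar)
        rho_p <- 2 * sin(pi * coupling$target_rho[i] / 6)
        amp <- sigma * abs(rho_p) / sqrt(1 - rho_p^2)
        log_mu[g, ] <- log_mu[g, ] + sign(coupling$target_rho[i]) * amp * z
      }
    }

    mu <- exp(sweep(log_mu, 2, log(lib), "+"))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
                     nrow = n_genes, dimnames = dimnames(mu))
    storage.mode(counts) <- "integer"

    truth <- list(de_genes = de_genes, signature_genes = signature_genes,
                  coupled_pairs = coupled_pairs, size_factors_true = lib)
    list(counts = counts, truth = truth)
  })
}

#' Default transcriptomic subtype DE programs
#'
#' Three usable ADM subtypes (hypoxia-like ADM1, no-special-type ADM2,
#' immune-like ADM3) each get a program of 3% of the genes (150 at the
#' default 5000-gene cohort) at |log2FC| = 2 with 15% down-regulated; the
#' tiny ADM4 gets a 1% program but is expected to be excluded from
#' one-vs-rest testing by its sample size.
#' @param n_genes Total gene count the programs scale against.
#' @return Named list of per-subtype configs.
#' @export
default_de_config <- function(n_genes = 5000) {
  main <- max(10L, round(0.03 * n_genes))
  list(
    ADM1 = list(n_genes = main, log2fc = 2, frac_down = 0.15),
    ADM2 = list(n_genes = main, log2fc = 2, frac_down = 0.15),
    ADM3 = list(n_genes = main, log2fc = 2, frac_down = 0.15),
    ADM4 = list(n_genes = max(5L, round(0.01 * n_genes)), log2fc = 2,
                frac_down = 0.15)
  )
}

#' Simulate disease-free survival for a sample sheet
#'
#' Event times are exponential with a per-group hazard; censoring is an
#' independent exponential whose rate is chosen so the expected fraction
#' censored equals `censor_rate`.
#'
#' @param sample_ids Character vector of sample ids.
#' @param group Named character vector sample -> group label.
#' @param hazard_by_group Named positive hazards (events per unit time).
#' @param censor_rate Expected censoring fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return data.frame(sample_id, dfs_time, dfs_event) with
#'   `dfs_event` 1 = event, 0 = censored.
#' @export
simulate_survival <- function(sample_ids, group, hazard_by_group,
                              censor_rate = 0.3, seed = 1) {
  if (any(hazard_by_group <= 0)) stop("hazards must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (!all(unique(group[sample_ids]) %in% names(hazard_by_group))) {
    stop("hazard_by_group must cover every group")
  }
  with_seed(seed, {
    lam <- hazard_by_group[group[sample_ids]]
    t_event <- stats::rexp(length(sample_ids), rate = lam)
    if (censor_rate > 0) {
      # P(censor) = c_rate when censoring rate = lam * r / (1 - r)
      lam_c <- lam * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(length(sample_ids), rate = lam_c)
    } else {
      t_cens <- rep(Inf, length(sample_ids))
    }
    data.frame(sample_id = sample_ids,
               dfs_time = pmin(t_event, t_cens),
               dfs_event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic PanNET-like cohort
#'
#' One call generating every input the pipeline consumes, with all planted
#' effects recorded in a single ground-truth ledger. The cohort has a
#' two-level structure: an alpha-like and an ADM methylation group, with
#' the ADM group split into transcriptomic subtypes ADM1 (hypoxia-like),
#' ADM2 (no special type), ADM3 (immune-like) and a 2-sample ADM4 that
#' downstream analyses are expected to set aside. ADM samples carry
#' global sub-telomeric/peri-centromeric hypomethylation and an
#' enhancer-biased DMP block; each subtype carries its own expression
#' program; a metastasis-like signature block is elevated in ADM1 and
#' ADM3; and a set of ADM1 genes is anti-correlated with their promoter
#' probe methylation.
#'
#' All randomness derives from the single `seed`.
#'
#' @param n_alpha,n_adm Methylation group sizes.
#' @param adm_split Named sizes of the transcriptomic subtypes (must sum
#'   to `n_adm`).
#' @param n_probes,n_genes Feature counts.
#' @param n_dmp,dmp_delta_beta,region_delta_beta,noise_sd Methylation
#'   effects, see [simulate_methylation()].
#' @param n_coupled,coupling_rho Number of planted promoter-coupled ADM1
#'   genes and their target Spearman correlation.
#' @param nb_dispersion NB dispersion of the count simulation.
#' @param hazard,censor_rate Survival parameters; a single hazard for all
#'   subtypes reproduces the equal-prognosis structure of ADM subtypes.
#' @param seed Master seed.
#' @return List: `genome`, `manifest`, `beta`, `counts`, `sheet`
#'   (sample sheet data.frame), `truth` (merged ground-truth ledger).
#' @export
simulate_cohort <- function(n_alpha = 30, n_adm = 60,
                            adm_split = c(ADM1 = 20, ADM2 = 20, ADM3 = 18, ADM4 = 2),
                            n_probes = 10000, n_genes = 5000,
                            n_dmp = 500, dmp_delta_beta = 0.3,
                            region_delta_beta = -0.15, noise_sd = 0.15,
                            n_coupled = 40, coupling_rho = -0.85,
                            nb_dispersion = 0.05,
                            hazard = 0.1, censor_rate = 0.3, seed = 1) {
  if (sum(adm_split) != n_adm) stop("adm_split must sum to n_adm")
  seeds <- derive_seeds(seed, 6, tag = "cohort")

  genome <- toy_genome()
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  manifest <- make_manifest(genome, n_probes, gene_ids = gene_ids,
                            seed = seeds[1])

  # couple ADM1 up-regulated genes to one of their promoter probes; the
  # probes get a variable mid-range baseline and are hypomethylated
  # specifically in ADM1 (logit shift -1.5, about -0.3 beta at mid-range),
  # so the anti-correlation carries the subtype structure the way promoter
  # hypomethylation does in hypoxic tumors
  prom <- manifest[manifest$state %in% c("active_promoter", "weak_promoter") &
                     !is.na(manifest$gene), ]
  prom <- prom[!duplicated(prom$gene), ]
  coupled_genes <- with_seed(seeds[3], sample(prom$gene, n_coupled))
  coupling <- data.frame(gene = coupled_genes,
                         probe = prom$probe_id[match(coupled_genes, prom$gene)],
                         target_rho = coupling_rho, stringsAsFactors = FALSE)

  meth <- simulate_methylation(manifest, genome,
                               groups = c(alpha_like = n_alpha, ADM = n_adm),
                               n_dmp = n_dmp, dmp_delta_beta = dmp_delta_beta,
                               region_delta_beta = region_delta_beta,
                               intermediate_probes = coupling$probe,
                               noise_sd = noise_sd, seed = seeds[2])

  samples <- names(meth$truth$sample_group)
  adm_samples <- samples[meth$truth$sample_group == "ADM"]
  subtype <- meth$truth$sample_group
  subtype[adm_samples] <- rep(names(adm_split), adm_split)
  adm1_samples <- names(subtype)[subtype == "ADM1"]
  lg <- log(meth$beta[coupling$probe, adm1_samples, drop = FALSE] /
              (1 - meth$beta[coupling$probe, adm1_samples, drop = FALSE]))
  meth$beta[coupling$probe, adm1_samples] <- 1 / (1 + exp(-(lg - 1.5)))
  meth$truth$coupled_probe_logit_shift <- stats::setNames(
    rep(-1.5, nrow(coupling)), coupling$probe)

  # coupled genes are planted as up-regulated members of ADM1's program so
  # every coupled pair is also a DEG of at least one subtype
  de_config <- default_de_config(n_genes)
  de_config$ADM1$genes <- coupled_genes
  de_config$ADM1$n_genes <- max(de_config$ADM1$n_genes, n_coupled)
  expr <- simulate_expression(subtype, n_genes = n_genes, de_config = de_config,
                              coupling = coupling, manifest = manifest,
                              beta = meth$beta, nb_dispersion = nb_dispersion,
                              seed = seeds[4])

  surv <- simulate_survival(samples, subtype,
                            hazard_by_group = stats::setNames(
                              rep(hazard, length(unique(subtype))), unique(subtype)),
                            censor_rate = censor_rate, seed = seeds[5])

  sheet <- with_seed(seeds[6], {
    is_adm <- subtype != "alpha_like"
    grade <- ifelse(is_adm,
                    sample(c("G1", "G2", "G3"), length(samples), TRUE, c(0.1, 0.6, 0.3)),
                    sample(c("G1", "G2", "G3"), length(samples), TRUE, c(0.6, 0.35, 0.05)))
    alt <- ifelse(is_adm,
                  sample(c("ALT+", "ALT-"), length(samples), TRUE, c(0.8, 0.2)),
                  sample(c("ALT+", "ALT-"), length(samples), TRUE, c(0.1, 0.9)))
    cna <- ifelse(is_adm,
                  sample(c("LOH", "stable"), length(samples), TRUE, c(0.7, 0.3)),
                  sample(c("LOH", "stable"), length(samples), TRUE, c(0.15, 0.85)))
    size <- exp(stats::rnorm(length(samples),
                             mean = ifelse(subtype == "ADM3", log(2.0), log(3.2)),
                             sd = 0.3))
    fun <- sample(c("non-functioning", "insulinoma", "VIPoma"),
                  length(samples), TRUE, c(0.9, 0.07, 0.03))
    data.frame(
      sample_id = samples,
      batch = "batch1",
      epigenetic_subtype = ifelse(is_adm, "ADM", "alpha_like"),
      transcriptomic_subtype = unname(subtype),
      menin_lost = TRUE,
      daxx_atrx_lost = ifelse(is_adm,
                              stats::runif(length(samples)) < 0.9,
                              stats::runif(length(samples)) < 0.1),
      grade = grade, alt_status = alt, cna_status = cna,
      functional_status = fun, tumor_size_cm = round(size, 2),
      stringsAsFactors = FALSE
    )
  })
  sheet <- merge(sheet, surv, by = "sample_id", sort = FALSE)
  sheet <- sheet[match(samples, sheet$sample_id), ]
  rownames(sheet) <- NULL

  truth <- c(meth$truth, expr$truth,
             list(sample_subtype = subtype,
                  hazard_by_group = stats::setNames(
                    rep(hazard, length(unique(subtype))), unique(subtype))))

  list(genome = genome, manifest = manifest, beta = meth$beta,
       counts = expr$counts, sheet = sheet, truth = truth)
}
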