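#' Configuration for the synthetic drought-study generator
#'
#' Bundles every knob of the seeded generator that emulates a multi-variety
#' drought experiment: a germination screen over a large germplasm panel, a
#' 4-variety x 4-timepoint physiological time course, an expression matrix
#' with planted co-expression modules whose latent activity tracks traits,
#' three differential-expression contrasts sharing a planted common
#' responsive gene set, and Ct tables consistent with the planted fold
#' changes.
#'
#' Each variety carries a latent tolerance `tau` in `[0, 1]`; every layer of
#' the simulation is a monotone function of `tau` plus noise, so recovery of
#' the planted ordering is a meaningful end-to-end check.
#'
#' @param seed integer master seed; all stage seeds derive from it.
#' @param n_varieties germplasm panel size for the germination screen.
#' @param tau named tolerance vector for the panel; default evenly spaced on
#'   `[0.05, 0.95]`.
#' @param focal_tau named tolerance for the four focal varieties carried into
#'   the seedling experiment (two tolerant, two sensitive).
#' @param n_seeds seeds sown per variety and treatment (three dishes of 30,
#'   pooled).
#' @param germination_floor stress germination retention at `tau = 0`.
#' @param timepoints stress sampling days.
#' @param n_reps biological replicates per cell.
#' @param noise_sd fractional replicate noise for trait measurements.
#' @param n_genes,n_modules expression matrix dimensions.
#' @param expr_noise_sd residual SD (log2 scale) around module factors.
#' @param module_trait_link tibble `module`, `trait`, `rho` describing which
#'   module's latent factor each trait tracks.
#' @param n_flip_genes genes whose correlation with the CAT-linked factor
#'   reverses sign between varieties (the tolerant-positive /
#'   sensitive-negative hub pattern).
#' @param n_shared_degs planted genes passing thresholds in all three
#'   contrasts.
#' @param n_specific_degs additional contrast-specific DEGs per contrast.
#' @param lfc_cut,p_cut thresholds the planted DEGs are built to pass.
#' @param qpcr_noise_sd technical Ct noise in cycles.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             n_varieties = 28,
                             tau = NULL,
                             focal_tau = c(MS = 0.9, MD = 0.8, HW = 0.3, HK = 0.2),
                             n_seeds = 90,
                             germination_floor = 0.2,
                             timepoints = c(3, 5, 7, 10),
                             n_reps = 3,
                             noise_sd = 0.02,
                             n_genes = 2000,
                             n_modules = 6,
                             expr_noise_sd = 0.3,
                             module_trait_link = NULL,
                             n_flip_genes = 6,
                             n_shared_degs = 150,
                             n_specific_degs = 100,
                             lfc_cut = 2,
                             p_cut = 0.05,
                             qpcr_noise_sd = 0.15) {
  if (is.null(tau)) {
    tau <- setNames(seq(0.05, 0.95, length.out = n_varieties),
                    sprintf("V%02d", seq_len(n_varieties)))
  }
  stopifnot(all(tau >= 0 & tau <= 1), all(focal_tau >= 0 & focal_tau <= 1))
  if (is.null(module_trait_link)) {
    n_regular <- n_modules - (n_flip_genes > 0)
    n_links <- min(3, n_regular)
    module_trait_link <- tibble::tibble(
      module = seq_len(n_links),
      trait = c("CAT", "PRO", "MDA")[seq_len(n_links)],
      rho = c(0.9, 0.85, -0.8)[seq_len(n_links)]
    )
  }
  structure(
    list(seed = seed, n_varieties = n_varieties, tau = tau,
         focal_tau = focal_tau, n_seeds = n_seeds,
         germination_floor = germination_floor, timepoints = timepoints,
         n_reps = n_reps, noise_sd = noise_sd, n_genes = n_genes,
         n_modules = n_modules, expr_noise_sd = expr_noise_sd,
         module_trait_link = module_trait_link,
         n_flip_genes = n_flip_genes, n_shared_degs = n_shared_degs,
         n_specific_degs = n_specific_degs, lfc_cut = lfc_cut,
         p_cut = p_cut, qpcr_noise_sd = qpcr_noise_sd),
    class = "generator_config"
  )
}

# run `expr` under a stage-specific seed derived from the master seed,
# restoring the caller's RNG state afterwards
with_stage_seed <- function(cfg, offset, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed((cfg$seed + offset) %% .Machine$integer.max)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(expr)
}

# daily germination schedule: early-peaked multinomial weights over 10 days
germination_schedule <- function() {
  w <- c(2, 8, 10, 6, 3, 1.5, 1, 0.6, 0.4, 0.2)
  w / sum(w)
}

#' Simulate a germination screen
#'
#' Control germination draws a high-probability binomial spread over an
#' early-peaked 10-day schedule; stress germination thins each variety's
#' counts binomially with retention `floor + (1 - floor) * tau`, so the
#' relative indices are monotone in the planted tolerance. Seedling
#' root/shoot lengths shrink under stress by the same retention factor.
#'
#' @param cfg a [generator_config()].
#' @return a list with `counts` (variety, treatment, day, newly_germinated,
#'   total_sown), `seedlings` (variety, treatment, replicate, root_mm,
#'   shoot_mm) and `tau` (the planted tolerance, for validation).
#' @export
simulate_germination <- function(cfg) {
  with_stage_seed(cfg, 101, {
    sched <- germination_schedule()
    days <- seq_along(sched)
    counts <- purrr::imap(cfg$tau, function(tau_v, v) {
      germ_c <- rbinom(1, cfg$n_seeds, 0.92)
      daily_c <- as.vector(stats::rmultinom(1, germ_c, sched))
      retain <- cfg$germination_floor + (1 - cfg$germination_floor) * tau_v
      daily_s <- rbinom(length(daily_c), daily_c, retain)
      tibble::tibble(
        variety = v,
        treatment = rep(c("control", "stress"), each = length(days)),
        day = rep(days, 2),
        newly_germinated = c(daily_c, daily_s),
        total_sown = cfg$n_seeds
      )
    }) |> purrr::list_rbind()
    seedlings <- purrr::imap(cfg$tau, function(tau_v, v) {
      retain <- cfg$germination_floor + (1 - cfg$germination_floor) * tau_v
      n <- 3
      tibble::tibble(
        variety = v,
        treatment = rep(c("control", "stress"), each = n),
        replicate = rep(seq_len(n), 2),
        root_mm = c(rnorm(n, 50, 2), rnorm(n, 50 * retain, 2)),
        shoot_mm = c(rnorm(n, 62, 2), rnorm(n, 62 * retain, 2))
      )
    }) |> purrr::list_rbind()
    list(counts = counts, seedlings = seedlings, tau = cfg$tau)
  })
}

# the fourteen-trait panel: control baseline, fractional change at tau = 1
# (tolerant) and tau = 0 (sensitive), loosely calibrated to the magnitudes a
# PEG-6000 seedling trial reports (growth and water status decline, damage
# markers and osmolytes/antioxidants rise, proline explosively so in
# tolerant lines)
trait_effect_table <- function() {
  tibble::tribble(
    ~trait,          ~baseline, ~effect_tol, ~effect_sens,
    "plant_height",       40,        -0.08,       -0.16,
    "fresh_weight",        2.5,      -0.28,       -0.58,
    "dry_weight",          0.4,      -0.40,       -0.55,
    "chlorophyll",         2.0,      -0.50,       -0.62,
    "RWC",                90,        -0.13,       -0.27,
    "REC",                12,         0.43,        1.23,
    "MDA",                 8,         0.30,        2.20,
    "PRO",                30,        27.0,         0.50,
    "GSH",               120,         1.20,        0.50,
    "SOD",               220,         1.30,        1.00,
    "POD",               800,         1.90,        0.90,
    "SP",                 14,         2.20,        1.30,
    "SS",                 20,         0.45,       -0.32,
    "CAT",               150,         1.40,        0.10
  )
}

#' Simulate the physiological trait time course
#'
#' Four focal varieties x two treatments x four timepoints x fourteen
#' traits, three replicates per cell. The stress effect on each trait ramps
#' linearly with stress duration and interpolates between a
#' sensitive-variety magnitude (`tau = 0`) and a tolerant-variety magnitude
#' (`tau = 1`); replicate noise is fractional Gaussian. Control cells do not
#' depend on `tau`.
#'
#' @param cfg a [generator_config()].
#' @return a list with `raw` (replicate-level tibble matching
#'   [summarize_traits()] input) and `tau` (planted focal tolerances).
#' @export
simulate_traits <- function(cfg) {
  with_stage_seed(cfg, 202, {
    eff <- trait_effect_table()
    grid <- tidyr::expand_grid(
      variety = names(cfg$focal_tau),
      treatment = c("CK", "PEG"),
      timepoint_d = cfg$timepoints,
      trait = eff$trait,
      replicate = seq_len(cfg$n_reps)
    ) |>
      dplyr::left_join(eff, by = "trait") |>
      dplyr::mutate(
        tau = cfg$focal_tau[.data$variety],
        ramp = .data$timepoint_d / max(cfg$timepoints),
        effect = .data$effect_sens +
          (.data$effect_tol - .data$effect_sens) * .data$tau,
        mean_value = .data$baseline *
          ifelse(.data$treatment == "PEG", 1 + .data$effect * .data$ramp, 1),
        value = .data$mean_value * (1 + rnorm(dplyr::n(), 0, cfg$noise_sd))
      )
    raw <- dplyr::select(grid, "variety", "treatment", "timepoint_d",
                         "trait", "replicate", "value")
    list(raw = raw, tau = cfg$focal_tau)
  })
}

#' Simulate an expression matrix with planted modules
#'
#' Twelve samples (tolerant and sensitive variety x control/stress x three
#' replicates), `n_genes` genes partitioned into `n_modules` planted
#' modules. Each module has a per-sample latent factor (with a mild stress
#' shift); member genes load on it with residual log2-scale noise. Linked
#' traits are generated as noisy linear functions of their module's factor
#' at the configured correlation. A designated set of "flip" genes in the
#' CAT-linked module loads positively in the tolerant variety and negatively
#' in the sensitive one, planting the cross-variety sign reversal.
#'
#' @param cfg a [generator_config()].
#' @return a list with `expr` (tibble: `gene` + one column per sample),
#'   `samples` (tibble: sample, variety, treatment, replicate), `traits`
#'   (tibble: `sample` + one numeric column per trait), `modules` (tibble:
#'   gene, module index), `flip_genes` (character).
#' @export
simulate_expression <- function(cfg) {
  with_stage_seed(cfg, 303, {
    varieties <- c(tolerant = names(cfg$focal_tau)[which.max(cfg$focal_tau)],
                   sensitive = names(cfg$focal_tau)[which.min(cfg$focal_tau)])
    samples <- tidyr::expand_grid(
      variety = unname(varieties), treatment = c("CK", "PEG"),
      replicate = 1:3
    ) |>
      dplyr::mutate(sample = paste(.data$variety, .data$treatment,
                                   .data$replicate, sep = "_"))
    ns <- nrow(samples)
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    # the last planted module is the small variety-discordant ("flip") module;
    # the regular genes are split evenly over the remaining modules
    n_regular <- cfg$n_modules - (cfg$n_flip_genes > 0)
    module_of <- c(
      sort(rep(seq_len(n_regular),
               length.out = cfg$n_genes - cfg$n_flip_genes)),
      rep(cfg$n_modules, cfg$n_flip_genes)
    )
    flip_genes <- genes[module_of == cfg$n_modules & cfg$n_flip_genes > 0]
    # per-module latent factors: random but orthogonalized across samples so
    # the planted programs are distinct by construction (at 12 samples,
    # i.i.d. draws can be accidentally collinear and the planted structure
    # would not be identifiable by any method), plus a mild module-specific
    # stress shift
    stress <- as.numeric(samples$treatment == "PEG")
    shift <- runif(n_regular, -0.4, 0.4)
    factors <- qr.Q(qr(matrix(rnorm(ns * n_regular), ns, n_regular))) *
      sqrt(ns)
    factors <- factors + outer(stress, shift)
    base_mu <- runif(cfg$n_genes, 3, 8)
    loading <- runif(cfg$n_genes, 0.85, 1.15)
    var_sign <- ifelse(samples$variety == varieties[["tolerant"]], 1, -1)
    z <- matrix(0, cfg$n_genes, ns, dimnames = list(genes, samples$sample))
    for (g in seq_len(cfg$n_genes)) {
      flip <- genes[g] %in% flip_genes
      # flip genes ride the first (trait-linked) factor with a
      # variety-dependent sign: positive in the tolerant variety, negative
      # in the sensitive one
      f <- factors[, if (flip) 1 else module_of[g]]
      s <- if (flip) var_sign else rep(1, ns)
      noise_sd <- if (flip) cfg$expr_noise_sd * 2 / 3 else cfg$expr_noise_sd
      z[g, ] <- base_mu[g] + loading[g] * f * s + rnorm(ns, 0, noise_sd)
    }
    expr_vals <- pmax(2^z - 1, 0)   # back to an FPKM-like non-negative scale
    if (any(cfg$module_trait_link$module > n_regular)) {
      abort("module_trait_link references a module beyond the regular modules",
            class = "droughtrank_input_error")
    }
    traits <- tibble::tibble(sample = samples$sample)
    for (i in seq_len(nrow(cfg$module_trait_link))) {
      link <- cfg$module_trait_link[i, ]
      f <- factors[, link$module]
      fz <- (f - mean(f)) / sd(f)
      traits[[link$trait]] <- link$rho * fz +
        sqrt(1 - link$rho^2) * rnorm(ns)
    }
    # unlinked traits: pure noise
    for (tr in setdiff(c("CAT", "PRO", "MDA", "SOD", "SP", "REC"),
                       names(traits))) {
      traits[[tr]] <- rnorm(ns)
    }
    list(
      expr = tibble::as_tibble(expr_vals, rownames = "gene"),
      samples = samples,
      traits = traits,
      modules = tibble::tibble(gene = genes, module = module_of),
      flip_genes = flip_genes,
      varieties = varieties
    )
  })
}

#' Simulate three differential-expression contrasts
#'
#' Three contrasts (sensitive stress vs control, tolerant stress vs control,
#' stress vs stress) over the same gene universe. A planted shared set
#' passes the configured thresholds in all three contrasts by construction;
#' each contrast gets additional specific DEGs; all remaining genes are null
#' with `p ~ U(0, 1)` and log2 fold changes drawn from `N(0, 0.5)` truncated
#' at +/-1.5 so that null genes can never cross the (default 2.0) magnitude
#' threshold — the noiseless-threshold regime in which filter + intersection
#' recovers the planted set exactly.
#'
#' @param cfg a [generator_config()].
#' @return a list with `tables` (tibble: contrast, gene, log2fc, pvalue),
#'   `shared_genes`, `specific_genes` (named list per contrast), and
#'   `planted_lfc` (tibble gene x contrast log2 fold changes).
#' @export
simulate_de_tables <- function(cfg) {
  with_stage_seed(cfg, 404, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    contrasts <- c("HK_PEG_vs_HK_CK", "MS_PEG_vs_MS_CK", "HK_PEG_vs_MS_PEG")
    shared <- sort(sample(genes, cfg$n_shared_degs))
    remaining <- setdiff(genes, shared)
    specific <- list()
    for (ct in contrasts) {
      specific[[ct]] <- sort(sample(remaining, cfg$n_specific_degs))
      remaining <- setdiff(remaining, specific[[ct]])
    }
    shared_sign <- sample(c(-1, 1), length(shared), replace = TRUE)
    tables <- purrr::map(contrasts, function(ct) {
      lfc <- rnorm(length(genes), 0, 0.5)
      lfc <- pmin(pmax(lfc, -1.5), 1.5)
      p <- runif(length(genes))
      names(lfc) <- names(p) <- genes
      lfc[shared] <- shared_sign * runif(length(shared), cfg$lfc_cut + 0.5,
                                         cfg$lfc_cut + 4)
      p[shared] <- 10^-runif(length(shared), 4, 8)
      sp <- specific[[ct]]
      lfc[sp] <- sample(c(-1, 1), length(sp), replace = TRUE) *
        runif(length(sp), cfg$lfc_cut + 0.5, cfg$lfc_cut + 4)
      p[sp] <- 10^-runif(length(sp), 4, 8)
      tibble::tibble(contrast = ct, gene = genes, log2fc = unname(lfc),
                     pvalue = unname(p))
    }) |> purrr::list_rbind()
    planted_lfc <- tables |>
      dplyr::filter(.data$gene %in% shared) |>
      dplyr::select("contrast", "gene", "log2fc")
    list(tables = tables, shared_genes = shared, specific_genes = specific,
         planted_lfc = planted_lfc)
  })
}

#' Simulate a gene-set annotation with planted enrichment signal
#'
#' Fabricates a GMT-style collection over the generator's gene universe:
#' a few "responsive" terms drawing most members from the planted shared
#' DEG set (so enrichment of the shared set has signal), the rest drawing
#' members uniformly.
#'
#' @param cfg a [generator_config()].
#' @param shared_genes the planted shared DEG set (from
#'   [simulate_de_tables()]).
#' @param n_sets total number of sets (default 20, of which 3 enriched).
#' @param set_size members per set.
#' @return a `gene_set_collection` whose universe is the full gene panel;
#'   enriched terms are named `RESP_*`.
#' @export
simulate_gene_sets <- function(cfg, shared_genes, n_sets = 20, set_size = 30) {
  with_stage_seed(cfg, 505, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    sets <- list()
    for (i in 1:3) {
      n_hit <- round(set_size * 0.7)
      sets[[sprintf("RESP_%02d", i)]] <- sort(unique(c(
        sample(shared_genes, min(n_hit, length(shared_genes))),
        sample(setdiff(genes, shared_genes), set_size - n_hit)
      )))
    }
    for (i in seq_len(n_sets - 3)) {
      sets[[sprintf("BG_%02d", i)]] <- sort(sample(genes, set_size))
    }
    gene_set_collection(sets, universe = genes)
  })
}

#' Simulate a qPCR Ct table from planted fold changes
#'
#' Ct values encode the planted log2 fold changes under perfect doubling:
#' stressed samples of a gene shift their Ct by `-log2fc` cycles relative to
#' control, the reference gene is constant across treatments, and Gaussian
#' cycle noise is added. Three biological x three technical replicates per
#' condition.
#'
#' @param cfg a [generator_config()].
#' @param planted data frame with columns `gene`, `log2fc` (one row per
#'   gene) giving the fold changes to encode.
#' @param reference_gene reference gene id (default `"UBC_ref"`).
#' @return a list with `ct` (tibble: gene, sample, treatment, bio_rep,
#'   tech_rep, ct) and `planted` (echoed).
#' @export
simulate_qpcr <- function(cfg, planted, reference_gene = "UBC_ref") {
  check_columns(planted, c("gene", "log2fc"), "planted fold-change table")
  with_stage_seed(cfg, 606, {
    base_ct <- setNames(runif(nrow(planted), 20, 26), planted$gene)
    grid <- tidyr::expand_grid(
      gene = c(planted$gene, reference_gene),
      treatment = c("CK", "PEG"),
      bio_rep = 1:3, tech_rep = 1:3
    ) |>
      dplyr::left_join(planted, by = "gene") |>
      dplyr::mutate(
        sample = paste(.data$treatment, .data$bio_rep, sep = "_"),
        true_ct = dplyr::case_when(
          .data$gene == reference_gene ~ 20,
          .data$treatment == "PEG" ~ base_ct[.data$gene] - .data$log2fc,
          TRUE ~ base_ct[.data$gene]
        ),
        ct = .data$true_ct + rnorm(dplyr::n(), 0, cfg$qpcr_noise_sd)
      ) |>
      dplyr::select("gene", "sample", "treatment", "bio_rep", "tech_rep", "ct")
    list(ct = grid, planted = planted, reference_gene = reference_gene)
  })
}

#' Generate the full synthetic study
#'
#' One seeded configuration produces every pipeline input plus the ground
#' truth needed to validate recovery: germination screen, trait time course,
#' expression matrix with planted modules and sign-flip genes, three DE
#' contrasts with a planted shared set, an annotation with planted
#' enrichment, and a qPCR table for six shared DEGs.
#'
#' @param cfg a [generator_config()].
#' @return a named list with components `germination`, `traits`,
#'   `expression`, `de`, `gene_sets`, `qpcr` and `config`.
#' @export
simulate_study <- function(cfg = generator_config()) {
  germ <- simulate_germination(cfg)
  traits <- simulate_traits(cfg)
  expr <- simulate_expression(cfg)
  de <- simulate_de_tables(cfg)
  gene_sets <- simulate_gene_sets(cfg, de$shared_genes)
  # validate six planted shared DEGs by qPCR in the sensitive-variety contrast
  qpcr_genes <- de$planted_lfc |>
    dplyr::filter(.data$contrast == "HK_PEG_vs_HK_CK") |>
    dplyr::slice_head(n = 6) |>
    dplyr::select("gene", "log2fc")
  qpcr <- simulate_qpcr(cfg, qpcr_genes)
  list(germination = germ, traits = traits, expression = expr, de = de,
       gene_sets = gene_sets, qpcr = qpcr, config = cfg)
}
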