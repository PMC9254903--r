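# Multi-cancer synthetic cohort generator with planted drivers. Emulates
# the data layers the real analysis consumes: near-diploid segmented
# copy-number profiles with focal events over planted genes, per-gene
# mutation events with elevated rates in planted drivers, recurrent fusion
# pairs, paired tumour/normal FPKM expression with a copy-number dosage
# effect and planted over/under-expression, and overall survival drawn
# from an exponential proportional-hazards model tied to expression.
# Every stochastic layer draws from its own child seed stream, so
# disabling one channel never perturbs another.

#' Default planted drivers for simulation
#'
#' Three multi-channel drivers (an amplified/mutated/fused overexpressed
#' gene, a deleted/mutated underexpressed prognostic gene, and an
#' amplified overexpressed prognostic gene), planted in every simulated
#' cancer type.
#'
#' @return A tibble (`gene_id`, `channel`, `cancer_type` = NA meaning
#'   every cancer type).
#' @export
default_planted_drivers <- function() {
  tibble::tribble(
    ~gene_id,  ~channel,
    "CHD7",    "scna_amp",
    "CHD7",    "mutation",
    "CHD7",    "fusion",
    "CHD7",    "de_up",
    "SMARCA4", "scna_del",
    "SMARCA4", "mutation",
    "SMARCA4", "de_down",
    "SMARCA4", "prognosis",
    "HELLS",   "scna_amp",
    "HELLS",   "de_up",
    "HELLS",   "prognosis"
  ) |> mutate(cancer_type = NA_character_)
}

#' Build a simulation configuration
#'
#' All distributional parameters of the generator, with defaults chosen to
#' emulate TCGA-like cohorts at desk scale: a near-diploid background
#' (arm-scale log2 ratios ~ Normal(0, 0.05)) straddled by the 0.1
#' amplitude floor used downstream, focal events of 0.5-5 Mb with carrier
#' fraction 0.4 and mean amplitude 0.5, a 1% background mutation rate with
#' an 8x driver multiplier (echoing an 8% driver frequency against ~1%
#' background), four planted fusion events per driver pair, a log-normal
#' FPKM baseline with unit copy-number dosage slope, a 1.5 log2-unit
#' planted expression shift, and exponential survival with ~40% events
#' under administrative-plus-dropout censoring.
#'
#' @param n_cancer_types Number of simulated cancer types (default 5).
#' @param cancer_types Optional labels (default `SIM01`, `SIM02`, ...).
#' @param n_tumour Tumour specimens per cancer type (default 200).
#' @param n_normal_pairs Matched normal specimens per cancer type
#'   (default 30; must be <= `n_tumour`).
#' @param panel Gene panel tibble (default [atpcr_panel()]).
#' @param n_decoys Number of decoy genes added so rankings are non-trivial
#'   (default 200).
#' @param planted Planted-driver tibble (`gene_id`, `channel`, optional
#'   `cancer_type`, NA = all); default [default_planted_drivers()].
#'   Channels: `scna_amp`, `scna_del`, `mutation`, `fusion`, `de_up`,
#'   `de_down`, `prognosis`.
#' @param scna,mutation,fusion,expression,survival Named lists overriding
#'   individual layer parameters (see the returned object for names).
#' @return A validated object of class `simulation_config`.
#' @export
simulation_config <- function(n_cancer_types = 5L,
                              cancer_types = NULL,
                              n_tumour = 200L,
                              n_normal_pairs = 30L,
                              panel = atpcr_panel(),
                              n_decoys = 200L,
                              planted = default_planted_drivers(),
                              scna = list(),
                              mutation = list(),
                              fusion = list(),
                              expression = list(),
                              survival = list()) {
  if (is.null(cancer_types)) {
    cancer_types <- sprintf("SIM%02d", seq_len(n_cancer_types))
  }
  n_cancer_types <- length(cancer_types)
  cfg <- list(
    cancer_types = cancer_types,
    n_tumour = rep_len(as.integer(n_tumour), n_cancer_types),
    n_normal_pairs = rep_len(as.integer(n_normal_pairs), n_cancer_types),
    panel = validate_gene_model(panel),
    n_decoys = as.integer(n_decoys),
    planted = as_tibble(planted),
    scna = modifyList(list(
      background_sd = 0.05,   # arm-scale log2-ratio SD
      focal_width = c(0.5e6, 5e6),
      f_amp = 0.4, mu_amp = 0.5,
      f_del = 0.4, mu_del = 0.5,
      amp_sd = 0.1
    ), scna),
    mutation = modifyList(list(
      lambda_bg = 0.01,       # background per-gene-per-specimen rate
      rho = 8,                # driver rate multiplier
      caller_alpha = c(0.001, 0.005, 0.01, 0.01, 0.05),
      caller_epsilon = 0.02
    ), mutation),
    fusion = modifyList(list(
      background_rate = 0.02, # expected background events per specimen
      planted_pair_count = 4L # events per planted driver pair per cancer
    ), fusion),
    expression = modifyList(list(
      base_mean = 3, base_sd = 1, # per-gene baseline log2 FPKM
      # shared tumour/normal patient effect; a nonzero value induces
      # cross-gene expression dependence (library-size-like), which is
      # realistic but breaks the independence assumed by per-run
      # calibration diagnostics -- off by default
      patient_sd = 0,
      sigma = 0.5,                # residual noise (log2 units)
      beta_cn = 1,                # dosage slope per unit copy log2 ratio
      delta = 1.5                 # planted tumour shift (log2 units)
    ), expression),
    survival = modifyList(list(
      lambda0 = log(2) / 730,  # baseline hazard per day (2-year median)
      theta = 0.7,             # log-hazard per SD of prognosis expression
      horizon = 3650,          # administrative censoring (days)
      dropout_ratio = 1.5      # dropout hazard relative to lambda0
    ), survival)
  )
  class(cfg) <- "simulation_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (nrow(cfg$planted) > 0) {
    require_columns(cfg$planted, c("gene_id", "channel"), "planted drivers")
    if (!"cancer_type" %in% names(cfg$planted)) {
      cfg$planted$cancer_type <- NA_character_
    }
    channels <- c("scna_amp", "scna_del", "mutation", "fusion", "de_up",
                  "de_down", "prognosis")
    bad <- setdiff(cfg$planted$channel, channels)
    if (length(bad) > 0) {
      abort(sprintf("unknown planted channel(s): %s",
                    paste(bad, collapse = ", ")))
    }
    off_panel <- setdiff(cfg$planted$gene_id, cfg$panel$gene_id)
    if (length(off_panel) > 0) {
      abort(sprintf("planted gene(s) not in panel: %s",
                    paste(off_panel, collapse = ", ")))
    }
    named <- stats::na.omit(unique(cfg$planted$cancer_type))
    if (length(setdiff(named, cfg$cancer_types)) > 0) {
      abort("planted cancer_type not among simulated cancer types")
    }
  } else if (!"cancer_type" %in% names(cfg$planted)) {
    cfg$planted <- tibble(gene_id = character(), channel = character(),
                          cancer_type = character())
  }
  with(cfg$scna, {
    stopifnot(background_sd >= 0, amp_sd >= 0, mu_amp >= 0, mu_del >= 0)
    if (f_amp < 0 || f_amp > 1 || f_del < 0 || f_del > 1) {
      abort("carrier fractions must lie in [0, 1]")
    }
  })
  if (cfg$mutation$lambda_bg < 0 || cfg$mutation$rho < 0) {
    abort("mutation rates must be >= 0")
  }
  if (cfg$fusion$background_rate < 0) abort("fusion rate must be >= 0")
  if (any(cfg$n_normal_pairs > cfg$n_tumour)) {
    abort("n_normal_pairs must be <= n_tumour")
  }
  if (cfg$fusion$planted_pair_count > min(cfg$n_tumour)) {
    abort("more planted fusion events than tumour specimens")
  }
  if (cfg$expression$sigma < 0 || cfg$survival$lambda0 <= 0) {
    abort("expression sigma must be >= 0 and baseline hazard > 0")
  }
  cfg
}

# Expand the planted table to explicit (cancer_type, gene_id, channel)
# rows; NA cancer_type means every simulated cancer type.
expand_planted <- function(cfg) {
  if (nrow(cfg$planted) == 0) {
    return(tibble(cancer_type = character(), gene_id = character(),
                  channel = character()))
  }
  cfg$planted |>
    mutate(cancer_type = purrr::map(.data$cancer_type, function(ct) {
      if (is.na(ct)) cfg$cancer_types else ct
    })) |>
    tidyr::unnest("cancer_type") |>
    select("cancer_type", "gene_id", "channel") |>
    arrange(.data$cancer_type, .data$gene_id, .data$channel)
}

#' Simulate a multi-cancer cohort with planted drivers
#'
#' Generates one `cohort_bundle` per configured cancer type plus the
#' ground truth. Identical `(config, seed)` yields identical output; every
#' layer of every cancer type draws from its own deterministic child
#' stream of the master seed.
#'
#' @param config A `simulation_config`.
#' @param seed Integer master seed.
#' @return A list with `bundles` (named list of `cohort_bundle`) and
#'   `truth` (class `synthetic_truth`: planted drivers, generator
#'   parameters, seed).
#' @export
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  config <- validate_sim_config(config)
  genome <- bind_rows(
    config$panel,
    if (config$n_decoys > 0) decoy_genes(config$n_decoys, config$panel)
  )
  planted <- expand_planted(config)
  bundles <- purrr::map(seq_along(config$cancer_types), function(i) {
    simulate_one_cancer(config, genome, planted, i, seed)
  })
  names(bundles) <- config$cancer_types
  truth <- structure(
    list(planted = planted, config = config, seed = as.integer(seed)),
    class = "synthetic_truth"
  )
  list(bundles = bundles, truth = truth)
}

#' Simulate a null cohort (no planted drivers)
#'
#' As [simulate_cohort()] with every planted effect removed; the truth
#' lists no drivers. Used for type-I-error style calibration.
#'
#' @inheritParams simulate_cohort
#' @export
null_cohort <- function(config, seed = 1L) {
  config$planted <- config$planted[0, ]
  simulate_cohort(config, seed)
}

simulate_one_cancer <- function(cfg, genome, planted_all, i, seed) {
  ct <- cfg$cancer_types[i]
  n_t <- cfg$n_tumour[i]
  n_p <- cfg$n_normal_pairs[i]
  planted <- filter(planted_all, .data$cancer_type == ct)
  patients <- sprintf("%s-P%03d", ct, seq_len(n_t))
  tumours <- paste0(patients, "-T")
  normals <- paste0(patients[seq_len(n_p)], "-N")

  segments <- sim_segments(cfg, genome, planted, ct, tumours, seed)
  mutations <- sim_mutations(cfg, genome, planted, ct, tumours, seed)
  fusions <- sim_fusions(cfg, genome, planted, ct, tumours, seed)
  gene_cn <- segments_to_gene_matrix(segments, genome, samples = tumours)
  expression <- sim_expression(cfg, genome, planted, ct, patients, tumours,
                               normals, gene_cn, seed)
  clinical <- sim_clinical(cfg, planted, ct, tumours, expression, seed)

  cohort_bundle(
    cancer_type = ct,
    gene_model = genome,
    segments = segments,
    mutations = mutations,
    fusions = fusions,
    expression = expression,
    clinical = clinical
  )
}

# Arm-scale background blocks plus focal events over planted genes.
sim_segments <- function(cfg, genome, planted, ct, tumours, seed) {
  lens <- chrom_lengths()
  chroms <- names(lens)
  arms <- tibble(
    chrom = rep(chroms, each = 2),
    start = as.integer(c(rbind(1, floor(lens / 2) + 1))),
    end = as.integer(c(rbind(floor(lens / 2), lens)))
  )
  scna_planted <- filter(planted, .data$channel %in% c("scna_amp",
                                                       "scna_del"))
  withr::with_seed(child_seed(seed, ct, "scna"), {
    n_arms <- nrow(arms)
    seg <- arms[rep(seq_len(n_arms), times = length(tumours)), ] |>
      mutate(sample_id = rep(tumours, each = n_arms)) |>
      mutate(
        log2_ratio = rnorm(dplyr::n(), 0, cfg$scna$background_sd),
        n_markers = as.integer((.data$end - .data$start + 1) %/% 5e4)
      )
    for (j in seq_len(nrow(scna_planted))) {
      g <- genome[match(scna_planted$gene_id[j], genome$gene_id), ]
      dir <- if (scna_planted$channel[j] == "scna_amp") 1 else -1
      f <- if (dir == 1) cfg$scna$f_amp else cfg$scna$f_del
      mu <- if (dir == 1) cfg$scna$mu_amp else cfg$scna$mu_del
      carriers <- tumours[runif(length(tumours)) < f]
      for (s in carriers) {
        width <- runif(1, cfg$scna$focal_width[1], cfg$scna$focal_width[2])
        gene_len <- g$end - g$start + 1
        offset <- runif(1) * max(0, width - gene_len)
        fs <- max(1, round(g$start - offset))
        fe <- fs + round(width) - 1
        amp <- dir * abs(rnorm(1, mu, cfg$scna$amp_sd))
        seg <- apply_focal(seg, s, g$chrom, fs, fe, amp)
      }
    }
    arrange(seg, .data$sample_id, .data$chrom, .data$start) |>
      select("sample_id", "chrom", "start", "end", "n_markers",
             "log2_ratio")
  })
}

# Split the segments of (sample, chrom) around [fs, fe] and add `amp` to
# the overlapped pieces, keeping segments non-overlapping.
apply_focal <- function(seg, sample, chrom, fs, fe, amp) {
  idx <- which(seg$sample_id == sample & seg$chrom == chrom &
                 seg$start <= fe & seg$end >= fs)
  if (length(idx) == 0) return(seg)
  pieces <- purrr::map(idx, function(k) {
    row <- seg[k, ]
    out <- list()
    if (row$start < fs) {
      left <- row
      left$end <- as.integer(fs - 1)
      out <- c(out, list(left))
    }
    mid <- row
    mid$start <- as.integer(max(row$start, fs))
    mid$end <- as.integer(min(row$end, fe))
    mid$log2_ratio <- mid$log2_ratio + amp
    out <- c(out, list(mid))
    if (row$end > fe) {
      right <- row
      right$start <- as.integer(fe + 1)
      out <- c(out, list(right))
    }
    bind_rows(out)
  })
  pieces <- bind_rows(pieces) |>
    mutate(n_markers = as.integer((.data$end - .data$start + 1) %/% 5e4))
  bind_rows(seg[-idx, ], pieces)
}

# Per-gene-per-specimen Bernoulli mutation events; planted drivers at
# lambda_bg * rho.
sim_mutations <- function(cfg, genome, planted, ct, tumours, seed) {
  classes <- c("missense", "nonsense", "frameshift_indel", "inframe_indel",
               "splice", "other")
  class_p <- c(0.6, 0.1, 0.1, 0.05, 0.1, 0.05)
  mut_genes <- planted$gene_id[planted$channel == "mutation"]
  rates <- ifelse(genome$gene_id %in% mut_genes,
                  pmin(1, cfg$mutation$lambda_bg * cfg$mutation$rho),
                  cfg$mutation$lambda_bg)
  withr::with_seed(child_seed(seed, ct, "mutation"), {
    hits <- matrix(
      runif(nrow(genome) * length(tumours)) <
        rep(rates, times = length(tumours)),
      nrow = nrow(genome)
    )
    hit_idx <- which(hits, arr.ind = TRUE)
    tibble(
      sample_id = tumours[hit_idx[, 2]],
      gene_id = genome$gene_id[hit_idx[, 1]],
      variant_class = sample(classes, nrow(hit_idx), replace = TRUE,
                             prob = class_p)
    ) |> arrange(.data$sample_id, .data$gene_id)
  })
}

# Background fusion events over random ordered pairs plus planted
# recurrent driver pairs (driver as the 5' partner).
sim_fusions <- function(cfg, genome, planted, ct, tumours, seed) {
  fus_genes <- planted$gene_id[planted$channel == "fusion"]
  withr::with_seed(child_seed(seed, ct, "fusion"), {
    n_bg <- rpois(1, cfg$fusion$background_rate * length(tumours))
    bg <- if (n_bg > 0) {
      pairs <- purrr::map(seq_len(n_bg), function(k) {
        sample(genome$gene_id, 2)
      })
      tibble(
        sample_id = sample(tumours, n_bg, replace = TRUE),
        cancer_type = ct,
        gene_5p = purrr::map_chr(pairs, 1),
        gene_3p = purrr::map_chr(pairs, 2)
      )
    } else {
      tibble(sample_id = character(), cancer_type = character(),
             gene_5p = character(), gene_3p = character())
    }
    planted_rows <- purrr::map(fus_genes, function(g) {
      tibble(
        sample_id = sample(tumours, cfg$fusion$planted_pair_count),
        cancer_type = ct,
        gene_5p = g,
        gene_3p = paste0("PRT_", g)
      )
    })
    bind_rows(bg, planted_rows) |>
      arrange(.data$sample_id, .data$gene_5p, .data$gene_3p)
  })
}

# Paired tumour/normal FPKM with copy-number dosage and planted shifts.
sim_expression <- function(cfg, genome, planted, ct, patients, tumours,
                           normals, gene_cn, seed) {
  ex <- cfg$expression
  n_g <- nrow(genome)
  de_shift <- rep(0, n_g)
  de_up <- planted$gene_id[planted$channel == "de_up"]
  de_dn <- planted$gene_id[planted$channel == "de_down"]
  de_shift[genome$gene_id %in% de_up] <- ex$delta
  de_shift[genome$gene_id %in% de_dn] <- -ex$delta
  cn <- as_cn_matrix(gene_cn)[genome$gene_id, tumours, drop = FALSE]
  withr::with_seed(child_seed(seed, ct, "expression"), {
    base <- rnorm(n_g, ex$base_mean, ex$base_sd)
    pat_eff <- setNames(rnorm(length(patients), 0, ex$patient_sd),
                        patients)
    tum_log2 <- base + ex$beta_cn * cn + de_shift +
      matrix(rnorm(n_g * length(tumours), 0, ex$sigma), nrow = n_g)
    tum_log2 <- sweep(tum_log2, 2,
                      pat_eff[sub("-T$", "", tumours)], `+`)
    nor_log2 <- base +
      matrix(rnorm(n_g * length(normals), 0, ex$sigma), nrow = n_g)
    nor_log2 <- sweep(nor_log2, 2,
                      pat_eff[sub("-N$", "", normals)], `+`)
    values <- as_tibble(cbind(
      as.data.frame(2^tum_log2) |> setNames(tumours),
      as.data.frame(2^nor_log2) |> setNames(normals)
    ))
    values <- bind_cols(tibble(gene_id = genome$gene_id), values)
    meta <- tibble(
      sample_id = c(tumours, normals),
      patient_id = sub("-[TN]$", "", c(tumours, normals)),
      tissue = c(rep("tumour", length(tumours)),
                 rep("normal", length(normals)))
    )
    list(values = values, sample_meta = meta)
  })
}

# Exponential proportional hazards on the standardized log2 expression of
# prognosis-channel genes; administrative plus dropout censoring.
sim_clinical <- function(cfg, planted, ct, tumours, expression, seed) {
  sv <- cfg$survival
  prog_genes <- planted$gene_id[planted$channel == "prognosis"]
  eta <- rep(0, length(tumours))
  if (length(prog_genes) > 0) {
    m <- as.matrix(
      expression$values[match(prog_genes, expression$values$gene_id),
                        tumours, drop = FALSE]
    )
    z <- t(scale(t(log2(m + 1))))
    z[!is.finite(z)] <- 0
    eta <- sv$theta * colSums(z)
  }
  withr::with_seed(child_seed(seed, ct, "survival"), {
    t_event <- rexp(length(tumours), rate = sv$lambda0 * exp(eta))
    t_drop <- rexp(length(tumours), rate = sv$lambda0 * sv$dropout_ratio)
    t_cens <- pmin(sv$horizon, t_drop)
    tibble(
      sample_id = tumours,
      os_time = pmax(pmin(t_event, t_cens), 0.5),
      os_event = as.integer(t_event <= t_cens)
    )
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> seed %d, %d planted (gene, cancer, channel) rows\n",
    x$seed, nrow(x$planted)
  ))
  if (nrow(x$planted) > 0) {
    print(count(x$planted, .data$gene_id, .data$cancer_type))
  }
  invisible(x)
}

#' Write the ground truth beside a simulated cohort
#'
#' @param truth A `synthetic_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(
      seed = truth$seed,
      planted = truth$planted,
      params = truth$config[c("cancer_types", "n_tumour",
                              "n_normal_pairs", "n_decoys")]
    ),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
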