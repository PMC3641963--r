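#' Simulation configuration for the synthetic methylome/expression generator
#'
#' Bundles every condition of the generative model: the planted coefficient
#' vector linking log transcriptional noise (log CV) to its predictors, the
#' marginal distributions of the predictors, the bisulfite sequencing layer
#' (CpG density, read coverage), the transposable-element (TE) content of
#' gene bodies, and the nested replicate structure used for the
#' biological/technical variance decomposition.
#'
#' @param n_genes number of genes on the toy chromosome.
#' @param n_arrays replicate expression arrays per tissue (>= 2).
#' @param n_bio biological samples in the nested-replicate design (>= 1).
#' @param n_tech technical replicates per biological sample (>= 1).
#' @param beta planted coefficients of log CV on
#'   `(intercept, log abundance, body methylation, promoter methylation,
#'   log gene length)`.
#' @param cpg_density CpG sites per kilobase of simulated feature sequence.
#' @param coverage_mean mean sequencing reads per CpG site (Poisson).
#' @param te_fraction fraction of gene-body bases covered by TEs, in `[0, 1)`.
#' @param noise_sd residual standard deviation of log CV around the planted
#'   linear predictor.
#' @param seed root integer seed; every generator draws from a named
#'   sub-stream derived from it.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of true
#'   expression abundance (array-intensity scale).
#' @param length_meanlog,length_sdlog,min_length log-normal gene length
#'   parameters (bases) and a lower truncation bound.
#' @param body_shape,prom_shape,te_shape `c(shape1, shape2)` of the Beta
#'   marginals for body, promoter and TE fractional methylation.
#' @param copula_rho Gaussian-copula correlations of body and promoter
#'   methylation with log abundance, mimicking the coupling between
#'   methylation and expression seen in real tissues.
#' @param gamma_bio planted coefficients of `log sigma^2_bio` on
#'   `(intercept, log abundance, body methylation, promoter methylation)`
#'   in the nested-replicate generator.
#' @param gamma_tech planted coefficients of `log sigma^2_tech` on
#'   `(intercept, log abundance)`; technical variation depends on abundance
#'   only.
#' @param site_heterogeneity if `TRUE`, per-site methylation within a feature
#'   is Beta-distributed around the feature truth instead of constant.
#' @param site_precision Beta precision (shape1 + shape2) used when
#'   `site_heterogeneity` is on.
#'
#' @return a validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 1)
#' truth <- simulate_truth(cfg)
#' head(truth)
sim_config <- function(n_genes = 500L,
                       n_arrays = 20L,
                       n_bio = 2L,
                       n_tech = 2L,
                       beta = c(intercept = 1.5, abundance = -0.55,
                                body = -0.30, promoter = 0.25, length = 0),
                       cpg_density = 10,
                       coverage_mean = 30,
                       te_fraction = 0.35,
                       noise_sd = 0.15,
                       seed = 1L,
                       abundance_meanlog = log(300),
                       abundance_sdlog = 1.2,
                       length_meanlog = log(15000),
                       length_sdlog = 0.9,
                       min_length = 2000L,
                       body_shape = c(3.5, 1.5),
                       prom_shape = c(0.8, 3),
                       te_shape = c(9, 1.5),
                       copula_rho = c(body = 0.3, promoter = -0.3),
                       gamma_bio = c(intercept = 2.2, abundance = -0.5,
                                     body = -2.0, promoter = 1.5),
                       gamma_tech = c(intercept = -1.5, abundance = -0.25),
                       site_heterogeneity = FALSE,
                       site_precision = 50) {
  assert_count(n_genes, "n_genes")
  assert_count(n_arrays, "n_arrays")
  assert_count(n_bio, "n_bio")
  assert_count(n_tech, "n_tech")
  if (length(beta) != 5L || !is.numeric(beta)) {
    stop("'beta' must be a numeric vector of length 5", call. = FALSE)
  }
  if (!is.numeric(cpg_density) || cpg_density <= 0) {
    stop("'cpg_density' must be > 0", call. = FALSE)
  }
  if (!is.numeric(coverage_mean) || coverage_mean <= 0) {
    stop("'coverage_mean' must be > 0", call. = FALSE)
  }
  assert_fraction(te_fraction, "te_fraction", open_upper = TRUE)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be >= 0", call. = FALSE)
  }
  if (length(gamma_bio) != 4L || length(gamma_tech) != 2L) {
    stop("'gamma_bio' must have 4 entries and 'gamma_tech' 2", call. = FALSE)
  }
  names(beta) <- c("intercept", "abundance", "body", "promoter", "length")
  names(gamma_bio) <- c("intercept", "abundance", "body", "promoter")
  names(gamma_tech) <- c("intercept", "abundance")
  structure(list(
    n_genes = as.integer(n_genes), n_arrays = as.integer(n_arrays),
    n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
    beta = beta, cpg_density = cpg_density, coverage_mean = coverage_mean,
    te_fraction = te_fraction, noise_sd = noise_sd, seed = as.integer(seed),
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    min_length = as.integer(min_length),
    body_shape = body_shape, prom_shape = prom_shape, te_shape = te_shape,
    copula_rho = copula_rho, gamma_bio = gamma_bio, gamma_tech = gamma_tech,
    site_heterogeneity = isTRUE(site_heterogeneity),
    site_precision = site_precision
  ), class = "sim_config")
}

#' Simulate the per-gene ground truth table
#'
#' Draws, for each gene, true expression abundance (log-normal), fractional
#' methylation of gene body, promoter and TE portion (Beta marginals, with a
#' Gaussian copula coupling body/promoter methylation to log abundance),
#' gene length (truncated log-normal) and the true log coefficient of
#' variation obtained from the planted linear predictor plus Gaussian
#' residual noise.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per gene: `gene_id`, `abundance`,
#'   `body_meth`, `promoter_meth`, `te_meth`, `length`, `log_cv`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  with_seed(sub_seed(config$seed, "truth"), {
    z_a <- rnorm(n)
    log_ab <- config$abundance_meanlog + config$abundance_sdlog * z_a
    rb <- config$copula_rho[["body"]]
    rp <- config$copula_rho[["promoter"]]
    z_b <- rb * z_a + sqrt(1 - rb^2) * rnorm(n)
    z_p <- rp * z_a + sqrt(1 - rp^2) * rnorm(n)
    body <- qbeta(pnorm(z_b), config$body_shape[1], config$body_shape[2])
    prom <- qbeta(pnorm(z_p), config$prom_shape[1], config$prom_shape[2])
    te <- qbeta(runif(n), config$te_shape[1], config$te_shape[2])
    len <- pmax(config$min_length,
                round(rlnorm(n, config$length_meanlog, config$length_sdlog)))
    b <- config$beta
    log_cv <- b[["intercept"]] + b[["abundance"]] * log_ab +
      b[["body"]] * body + b[["promoter"]] * prom +
      b[["length"]] * log(len) + rnorm(n, 0, config$noise_sd)
    data.frame(
      gene_id = sprintf("g%05d", seq_len(n)),
      abundance = exp(log_ab),
      body_meth = body,
      promoter_meth = prom,
      te_meth = te,
      length = as.integer(len),
      log_cv = log_cv,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate gene models and TE intervals on a toy chromosome
#'
#' Lays non-overlapping gene bodies head-to-tail on a single linear
#' chromosome (`chrS`), with intergenic gaps wide enough that promoter
#' windows never reach a neighbouring gene. About 30% of genes receive a
#' second transcript that is a strict sub-interval of the first, so that
#' longest-transcript selection is exercised and unambiguous. TE intervals
#' are placed inside gene bodies by selecting 200-bp blocks independently
#' with probability `te_fraction`, so aggregate TE coverage of body bases
#' converges to `te_fraction`.
#'
#' @param config a [sim_config()].
#' @param truth optional [simulate_truth()] output; generated from `config`
#'   when omitted (gene lengths must come from the same truth table used
#'   downstream).
#' @return list with `genes` (a `GRanges` of transcripts with `gene_id` and
#'   `tx_id` metadata; several rows per gene when alternative transcripts
#'   exist) and `tes` (a `GRanges` of TE intervals).
#' @export
simulate_annotations <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- simulate_truth(config)
  if (nrow(truth) != config$n_genes) {
    stop("truth table does not match config$n_genes", call. = FALSE)
  }
  with_seed(sub_seed(config$seed, "annotations"), {
    n <- config$n_genes
    len <- truth$length
    # gaps wide enough that promoter windows (1.5 kb each way) never touch
    # a neighbouring gene or each other
    gaps <- 3500L + rpois(n, 500)
    starts <- cumsum(as.numeric(gaps)) + cumsum(c(0, as.numeric(len[-n])))
    starts <- as.integer(starts)  # 0-based starts
    ends <- starts + len          # 0-based half-open ends
    strand <- sample(c("+", "-"), n, replace = TRUE)

    tx_start <- starts
    tx_end <- ends
    gene_id <- truth$gene_id
    tx_id <- paste0(gene_id, ".t1")

    # alternative transcripts: strict sub-intervals of the primary one
    alt <- which(runif(n) < 0.3 & len >= 400L)
    if (length(alt)) {
      d1 <- sapply(len[alt], function(L) sample.int(max(1L, L %/% 4L), 1L))
      d2 <- sapply(len[alt], function(L) sample.int(max(1L, L %/% 4L), 1L))
      tx_start <- c(tx_start, starts[alt] + d1)
      tx_end <- c(tx_end, ends[alt] - d2)
      gene_id <- c(gene_id, truth$gene_id[alt])
      tx_id <- c(tx_id, paste0(truth$gene_id[alt], ".t2"))
      strand <- c(strand, strand[alt])
    }
    ord <- order(gene_id, tx_id)
    genes <- GenomicRanges::GRanges(
      seqnames = "chrS",
      ranges = IRanges::IRanges(start = tx_start[ord] + 1L, end = tx_end[ord]),
      strand = strand[ord]
    )
    S4Vectors::mcols(genes)$gene_id <- gene_id[ord]
    S4Vectors::mcols(genes)$tx_id <- tx_id[ord]

    # TE blocks inside gene bodies
    te_start <- integer(0); te_end <- integer(0)
    if (config$te_fraction > 0) {
      block <- 200L
      for (i in seq_len(n)) {
        nb <- max(1L, len[i] %/% block)
        sel <- which(runif(nb) < config$te_fraction)
        if (!length(sel)) next
        bs <- starts[i] + (sel - 1L) * block
        be <- pmin(bs + block, ends[i])
        te_start <- c(te_start, bs)
        te_end <- c(te_end, be)
      }
    }
    tes <- GenomicRanges::GRanges(
      seqnames = if (length(te_start)) "chrS" else character(0),
      ranges = IRanges::IRanges(start = te_start + 1L, end = te_end)
    )
    tes <- GenomicRanges::reduce(tes)
    list(genes = genes, tes = tes)
  })
}

# Sample k distinct genomic positions (1-based) uniformly from an IRanges set.
sample_positions <- function(ir, k) {
  w <- IRanges::width(ir)
  total <- sum(w)
  if (total == 0L || k == 0L) return(integer(0))
  k <- min(k, total)
  off <- sort(sample.int(total, k))
  cum <- cumsum(w)
  idx <- findInterval(off - 1L, c(0L, cum), rightmost.closed = FALSE)
  IRanges::start(ir)[idx] + (off - c(0L, cum)[idx] - 1L)
}

#' Simulate a per-CpG bisulfite call table
#'
#' Places CpG sites at `cpg_density` sites/kb within gene bodies, promoter
#' windows and TE intervals; draws per-site read coverage from a Poisson
#' distribution with mean `coverage_mean` (zero-coverage sites are emitted,
#' to exercise missing-data handling downstream); and draws methylated
#' ('C') read counts binomially with success probability equal to the
#' enclosing feature's true methylation fraction. Where features overlap,
#' site truth is assigned with priority promoter > TE > gene body (the
#' TSS-proximal methylation state wins, as unmethylated promoter regions do
#' in real methylomes even over repeats). Each site is annotated with a
#' random strand.
#'
#' @param config a [sim_config()].
#' @param annotations output of [simulate_annotations()].
#' @param truth matching [simulate_truth()] table.
#' @return data.frame of calls: `chrom`, `pos` (1-based), `strand`,
#'   `c_reads`, `t_reads`.
#' @export
simulate_methylome <- function(config, annotations, truth) {
  stopifnot(inherits(config, "sim_config"))
  genes <- annotations$genes
  tes <- GenomicRanges::reduce(annotations$tes)
  models <- select_longest_transcript(genes)
  ids <- S4Vectors::mcols(models)$gene_id
  missing_truth <- setdiff(ids, truth$gene_id)
  if (length(missing_truth)) {
    stop("missing truth row for gene(s): ",
         paste(head(missing_truth, 5), collapse = ", "), call. = FALSE)
  }
  truth <- truth[match(ids, truth$gene_id), ]
  proms <- promoter_interval(models)
  p_site <- min(1, config$cpg_density / 1000)

  with_seed(sub_seed(config$seed, "methylome"), {
    pos <- integer(0); m <- numeric(0)
    te_ir <- IRanges::ranges(tes)
    for (i in seq_along(models)) {
      body <- IRanges::ranges(models[i])
      prom <- IRanges::ranges(proms[i])
      r_prom <- prom
      r_te <- IRanges::setdiff(IRanges::intersect(te_ir, body), prom)
      r_body <- IRanges::setdiff(IRanges::setdiff(body, te_ir), prom)
      for (reg in list(list(r = r_te, m = truth$te_meth[i]),
                       list(r = r_prom, m = truth$promoter_meth[i]),
                       list(r = r_body, m = truth$body_meth[i]))) {
        w <- sum(IRanges::width(reg$r))
        if (w == 0L) next
        k <- rbinom(1L, w, p_site)
        if (k == 0L) next
        pos <- c(pos, sample_positions(reg$r, k))
        m <- c(m, rep(reg$m, k))
      }
    }
    ord <- order(pos)
    pos <- pos[ord]; m <- m[ord]
    cov <- rpois(length(pos), config$coverage_mean)
    if (config$site_heterogeneity) {
      prec <- config$site_precision
      mm <- pmin(pmax(m, 1e-9), 1 - 1e-9)
      m <- rbeta(length(m), mm * prec, (1 - mm) * prec)
    }
    c_reads <- rbinom(length(pos), cov, m)
    data.frame(
      chrom = "chrS",
      pos = pos,
      strand = sample(c("+", "-"), length(pos), replace = TRUE),
      c_reads = c_reads,
      t_reads = cov - c_reads,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a replicate expression matrix for one tissue
#'
#' For each gene, replicate array intensities are drawn log-normally with
#' mean equal to the gene's true abundance and coefficient of variation
#' `exp(log_cv)` from the truth table, using the exact log-normal moment
#' relations (`sigma^2 = log(1 + cv^2)`, `mu = log(mean) - sigma^2/2`). The
#' planted regression of log CV on abundance, methylation and length is
#' therefore recoverable from the matrix by [expression_noise()] plus
#' [fit_ols()].
#'
#' @param config a [sim_config()] (needs `n_arrays >= 2`).
#' @param truth matching [simulate_truth()] table.
#' @param tissue tissue label attached to the matrix.
#' @return numeric matrix (genes x arrays) with `tissue` and `qc_state`
#'   attributes.
#' @export
simulate_expression <- function(config, truth, tissue = "tissueA") {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_arrays < 2L) {
    stop("n_arrays must be >= 2: CV is undefined for a single array",
         call. = FALSE)
  }
  if (any(!is.finite(truth$abundance)) || any(truth$abundance <= 0)) {
    stop("truth abundances must be positive", call. = FALSE)
  }
  with_seed(sub_seed(config$seed, paste0("expression-", tissue)), {
    n <- nrow(truth); k <- config$n_arrays
    cv <- exp(truth$log_cv)
    s2 <- log(1 + cv^2)
    mu <- log(truth$abundance) - s2 / 2
    vals <- rlnorm(n * k, meanlog = rep(mu, k), sdlog = rep(sqrt(s2), k))
    mat <- matrix(vals, nrow = n, ncol = k,
                  dimnames = list(truth$gene_id,
                                  sprintf("%s_arr%02d", tissue, seq_len(k))))
    attr(mat, "tissue") <- tissue
    attr(mat, "qc_state") <- "raw"
    mat
  })
}

#' Simulate nested technical-within-biological replicate expression
#'
#' Generates, per gene, `y_ij = mean + b_i + e_ij` on the log-intensity
#' scale, with `b_i ~ N(0, sigma^2_bio)` and `e_ij ~ N(0, sigma^2_tech)`.
#' `log sigma^2_bio` follows the planted `gamma_bio` coefficients on log
#' abundance, body methylation and promoter methylation, while
#' `log sigma^2_tech` depends on abundance only (`gamma_tech`), so the
#' biological/technical decomposition models can recover the methylation
#' effects from the biological component alone.
#'
#' @param config a [sim_config()] with `n_bio >= 2` and `n_tech >= 2`.
#' @param truth matching [simulate_truth()] table.
#' @param sigma_bio,sigma_tech optional per-gene standard-deviation
#'   overrides (length 1 or `nrow(truth)`), bypassing the planted gamma
#'   models; used for degenerate-case checks.
#' @return long data.frame: `gene_id`, `bio` (sample index), `tech`
#'   (replicate index), `value`.
#' @export
simulate_nested_replicates <- function(config, truth,
                                       sigma_bio = NULL, sigma_tech = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_bio < 2L || config$n_tech < 2L) {
    stop("n_bio and n_tech must both be >= 2", call. = FALSE)
  }
  n <- nrow(truth)
  la <- log(truth$abundance)
  if (is.null(sigma_bio)) {
    g <- config$gamma_bio
    sigma_bio <- exp(0.5 * (g[["intercept"]] + g[["abundance"]] * la +
                            g[["body"]] * truth$body_meth +
                            g[["promoter"]] * truth$promoter_meth))
  }
  if (is.null(sigma_tech)) {
    h <- config$gamma_tech
    sigma_tech <- exp(0.5 * (h[["intercept"]] + h[["abundance"]] * la))
  }
  sigma_bio <- rep_len(sigma_bio, n)
  sigma_tech <- rep_len(sigma_tech, n)
  nb <- config$n_bio; nt <- config$n_tech
  with_seed(sub_seed(config$seed, "nested"), {
    b <- matrix(rnorm(n * nb, 0, rep(sigma_bio, nb)), n, nb)
    out <- expand.grid(tech = seq_len(nt), bio = seq_len(nb),
                       gene = seq_len(n))
    e <- rnorm(nrow(out), 0, sigma_tech[out$gene])
    data.frame(
      gene_id = truth$gene_id[out$gene],
      bio = out$bio,
      tech = out$tech,
      value = la[out$gene] + b[cbind(out$gene, out$bio)] + e,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a pure count-noise expression matrix
#'
#' Replicate values are independent Poisson counts around a per-gene rate
#' drawn log-uniformly from `lambda_range`. Because Poisson variance equals
#' the mean, the CV is `1/sqrt(lambda)` and the regression of log CV on log
#' mean has slope -1/2 — the classical noise-abundance scaling law.
#'
#' @param n_genes,n_arrays matrix dimensions.
#' @param lambda_range range of per-gene Poisson rates (log-uniform draw).
#' @param seed integer seed.
#' @return numeric matrix (genes x arrays).
#' @export
simulate_count_matrix <- function(n_genes = 2000L, n_arrays = 20L,
                                  lambda_range = c(10, 1e4), seed = 1L) {
  assert_count(n_genes, "n_genes")
  assert_count(n_arrays, "n_arrays", min = 2L)
  with_seed(sub_seed(seed, "counts"), {
    lambda <- exp(runif(n_genes, log(lambda_range[1]), log(lambda_range[2])))
    mat <- matrix(rpois(n_genes * n_arrays, rep(lambda, n_arrays)),
                  nrow = n_genes,
                  dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                                  sprintf("arr%02d", seq_len(n_arrays))))
    mat
  })
}

#' Simulate a stacked per-individual methylation analysis table
#'
#' Emulates re-measuring gene body methylation in several individuals:
#' each individual's body methylation is the shared truth plus small
#' measurement noise (clipped to `[0, 1]`), and log CV is generated with a
#' per-individual body-methylation slope `beta_body + dev_i`, where the
#' deviations `dev_i` are evenly spaced in `[-slope_dev, slope_dev]`.
#' `slope_dev = 0` is the null of no between-individual methylation effect.
#'
#' @param config a [sim_config()].
#' @param truth matching [simulate_truth()] table.
#' @param n_individuals number of individuals (>= 2).
#' @param slope_dev half-range of per-individual body-methylation slope
#'   deviations; 0 for the null.
#' @param meas_sd standard deviation of per-individual methylation
#'   measurement noise.
#' @return data.frame: `gene_id`, `individual` (factor), `log_cv`,
#'   `log_abundance`, `log_length`, `body_meth`, `promoter_meth`.
#' @export
simulate_individual_table <- function(config, truth, n_individuals = 3L,
                                      slope_dev = 0, meas_sd = 0.02) {
  stopifnot(inherits(config, "sim_config"))
  assert_count(n_individuals, "n_individuals", min = 2L)
  b <- config$beta
  devs <- if (n_individuals == 1L) 0 else
    seq(-slope_dev, slope_dev, length.out = n_individuals)
  with_seed(sub_seed(config$seed, "individuals"), {
    out <- vector("list", n_individuals)
    for (i in seq_len(n_individuals)) {
      bm <- pmin(1, pmax(0, truth$body_meth + rnorm(nrow(truth), 0, meas_sd)))
      y <- b[["intercept"]] + b[["abundance"]] * log(truth$abundance) +
        (b[["body"]] + devs[i]) * bm +
        b[["promoter"]] * truth$promoter_meth +
        b[["length"]] * log(truth$length) +
        rnorm(nrow(truth), 0, config$noise_sd)
      out[[i]] <- data.frame(
        gene_id = truth$gene_id,
        individual = sprintf("ind%d", i),
        log_cv = y,
        log_abundance = log(truth$abundance),
        log_length = log(truth$length),
        body_meth = bm,
        promoter_meth = truth$promoter_meth,
        stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, out)
    res$individual <- factor(res$individual)
    res
  })
}

#' Simulate a complete scenario
#'
#' Runs every generator under one configuration: truth table, annotations,
#' CpG call table, replicate expression matrix and nested replicate table.
#'
#' @param config a [sim_config()].
#' @param tissue tissue label for the expression matrix.
#' @return list with elements `config`, `truth`, `annotations`, `calls`,
#'   `expression`, `nested`.
#' @export
simulate_scenario <- function(config, tissue = "tissueA") {
  truth <- simulate_truth(config)
  ann <- simulate_annotations(config, truth)
  calls <- simulate_methylome(config, ann, truth)
  expr <- simulate_expression(config, truth, tissue = tissue)
  nested <- simulate_nested_replicates(config, truth)
  list(config = config, truth = truth, annotations = ann,
       calls = calls, expression = expr, nested = nested)
}
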