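#' Configuration for a synthetic cohort
#'
#' Describes a cohort emulating the statistical structure the pipeline
#' assumes: correlated physical-activity (PA) features, symmetric
#' partial-correlation netmats vectorized to Fisher-z functional
#' connectivity (FC) edges, strictly positive regional gray-matter volumes
#' (GMV), confounder effects on every block, a low-dimensional shared
#' latent structure between PA and each imaging block with a controllable
#' population canonical correlation, and rare binary disease outcomes.
#'
#' The shared structure is a linear Gaussian factor model: for each
#' planted mode, one standard-normal latent loads on orthonormal weight
#' directions in the PA block and in each imaging block, with loading
#' magnitudes solved in closed form so the population canonical
#' correlation of the residualized blocks equals `rho` exactly
#' (see [population_canonical_correlations()]).  Confounders are generated
#' independently of the latents, so residualization leaves the planted
#' correlations untouched.
#'
#' @param n_participants cohort size (positive integer).
#' @param n_pa number of PA features (default 11, the canonical set).
#' @param n_fc_nodes netmat nodes; FC edge count is
#'   `n_fc_nodes*(n_fc_nodes-1)/2` (55 nodes -> 1485 edges).
#' @param n_gmv number of gray-matter regions (default 139).
#' @param n_confounders number of confounder columns shared by all blocks;
#'   the first is binary (sex-like), the rest continuous (age-like,
#'   motion-like), at least 2.
#' @param latent_spec list of planted modes.  Each element is a list with
#'   `rho` (target population canonical correlation in [0,1)) and optional
#'   unit-direction vectors `w_pa`, `w_fc`, `w_gmv` (drawn at random, then
#'   orthonormalized across modes, when omitted).  An empty list plants no
#'   shared structure.
#' @param noise_scales named numeric vector of independent-noise standard
#'   deviations per block, entries `pa`, `fc`, `gmv`, all strictly positive.
#' @param confounder_strength scale of the (random, seed-determined)
#'   confounder effects on each block.
#' @param pa_collinearity strength of an extra common factor within the PA
#'   block, orthogonal to the planted directions, emulating the strong
#'   multicollinearity of real accelerometry summaries.
#' @param fc_edge_scale fixed scalar applied to the latent FC field before
#'   it becomes Fisher-z edges; keeps netmat correlations comfortably
#'   inside (-0.95, 0.95) without affecting canonical correlations.
#' @param gmv_scale scale of the Gaussian field exponentiated into
#'   positive volumes.
#' @param disease_spec named list of per-disease specifications, each a
#'   list with `prevalence` in (0,1) and coefficient vectors
#'   `beta_conf`, `beta_pa`, `beta_idp` (over standardized columns of the
#'   confounder, PA and FC-edge blocks; `beta_idp` may be a named scalar
#'   strength instead of a full vector).  Defaults plant
#'   confounder+PA-driven risk at the four prevalences typical of a
#'   middle-aged cohort: diabetes 4.5%, stroke 2.3%, CHD 3.3%,
#'   cancer 12.5%.
#' @param keep_netmats store per-participant netmats as a list of matrices
#'   (memory-heavy; they can always be rebuilt via [cohort_netmat()]).
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the config.
#' @return object of class `cohort_config`.
#' @seealso [generate_cohort()], [population_canonical_correlations()]
#' @export
cohort_config <- function(n_participants,
                          n_pa = 11L,
                          n_fc_nodes = 55L,
                          n_gmv = 139L,
                          n_confounders = 3L,
                          latent_spec = list(list(rho = 0.5)),
                          noise_scales = c(pa = 1, fc = 1, gmv = 1),
                          confounder_strength = 0.5,
                          pa_collinearity = 0.8,
                          fc_edge_scale = 0.25,
                          gmv_scale = 0.1,
                          disease_spec = default_disease_spec(),
                          keep_netmats = FALSE,
                          seed = 1L) {
  chk_posint <- function(x, field) {
    if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x)) {
      config_error(field, "must be a positive integer")
    }
    as.integer(x)
  }
  n_participants <- chk_posint(n_participants, "n_participants")
  n_pa <- chk_posint(n_pa, "n_pa")
  n_fc_nodes <- chk_posint(n_fc_nodes, "n_fc_nodes")
  n_gmv <- chk_posint(n_gmv, "n_gmv")
  n_confounders <- chk_posint(n_confounders, "n_confounders")
  if (n_confounders < 2L) config_error("n_confounders", "must be at least 2")

  n_fc <- (n_fc_nodes * (n_fc_nodes - 1L)) %/% 2L
  dims <- c(pa = n_pa, fc = n_fc, gmv = n_gmv)

  if (!is.list(latent_spec)) config_error("latent_spec", "must be a list")
  for (i in seq_along(latent_spec)) {
    m <- latent_spec[[i]]
    if (is.null(m$rho) || !is.finite(m$rho) || m$rho < 0 || m$rho >= 1) {
      config_error("latent_spec", sprintf("mode %d: rho must lie in [0, 1)", i))
    }
    for (blk in c("pa", "fc", "gmv")) {
      w <- m[[paste0("w_", blk)]]
      if (!is.null(w) && length(w) != dims[[blk]]) {
        config_error("latent_spec",
                     sprintf("mode %d: w_%s must have length %d", i, blk, dims[[blk]]))
      }
    }
  }
  if (length(latent_spec) > min(dims)) {
    config_error("latent_spec", "has more modes than the smallest block dimension")
  }

  if (!all(c("pa", "fc", "gmv") %in% names(noise_scales))) {
    config_error("noise_scales", "must name pa, fc and gmv")
  }
  if (any(!is.finite(noise_scales)) || any(noise_scales <= 0)) {
    config_error("noise_scales", "must be strictly positive")
  }

  for (d in names(disease_spec)) {
    pr <- disease_spec[[d]]$prevalence
    if (is.null(pr) || !is.finite(pr) || pr <= 0 || pr >= 1) {
      config_error("disease_spec", sprintf("'%s': prevalence must lie in (0, 1)", d))
    }
  }

  structure(
    list(n_participants = n_participants, n_pa = n_pa,
         n_fc_nodes = n_fc_nodes, n_fc = n_fc, n_gmv = n_gmv,
         n_confounders = n_confounders, latent_spec = latent_spec,
         noise_scales = noise_scales[c("pa", "fc", "gmv")],
         confounder_strength = confounder_strength,
         pa_collinearity = pa_collinearity,
         fc_edge_scale = fc_edge_scale, gmv_scale = gmv_scale,
         disease_spec = disease_spec, keep_netmats = isTRUE(keep_netmats),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Default disease-generating specification
#'
#' Four prevalent conditions with risk driven by confounders and PA only
#' (no imaging contribution), at prevalences 4.5%, 2.3%, 3.3% and 12.5%.
#' Coefficients act on standardized covariates, so they are log-odds per
#' SD.
#'
#' @return named list usable as `disease_spec` in [cohort_config()].
#' @export
default_disease_spec <- function() {
  base <- function(prev, b_pa) {
    list(prevalence = prev,
         beta_conf = c(0.3, 0.4, 0),
         beta_pa = b_pa,
         beta_idp = 0)
  }
  # PA coefficients in canonical column order:
  # TLAC LIPA MVPA SBout ABout SATP ASTP DARE M10 L5 RA
  list(
    diabetes = base(0.045, c(-0.5, 0, -0.3, 0.3, 0, 0, 0.2, 0, -0.3, 0, 0)),
    stroke   = base(0.023, c(-0.3, 0, -0.2, 0.2, 0, 0, 0.1, 0, -0.2, 0, 0)),
    chd      = base(0.033, c(-0.4, 0, -0.3, 0.25, 0, 0, 0.15, 0, -0.25, 0, 0)),
    cancer   = base(0.125, c(-0.15, 0, -0.1, 0.1, 0, 0, 0.05, 0, -0.1, 0, 0))
  )
}

# canonical PA feature names, in conventional reporting order
pa_feature_names <- function() {
  c("TLAC", "LIPA", "MVPA", "SBout", "ABout",
    "SATP", "ASTP", "DARE", "M10", "L5", "RA")
}

# plausible marginal location/scale applied to the standardized PA field so
# the feature table lands on realistic units (minutes, probabilities, ...)
pa_marginals <- function(n_pa) {
  mu <- c(2500, 300, 40, 20, 8, 0.45, 0.25, 0.75, 2.5, 0.3, 0.8)
  sg <- c(300, 90, 30, 8, 3, 0.10, 0.08, 0.05, 0.5, 0.2, 0.1)
  if (n_pa == 11L) return(list(mu = mu, sigma = sg, names = pa_feature_names()))
  list(mu = rep(0, n_pa), sigma = rep(1, n_pa),
       names = paste0("PA", seq_len(n_pa)))
}

# Build, per block, the weight matrix W (dim x n_modes) whose columns are
# orthonormal directions scaled so the population canonical correlation of
# mode m equals latent_spec[[m]]$rho.  With orthonormal directions u_m,
# loading c_m and isotropic noise sd s, the whitened cross-covariance
# singular value of mode m is
#   (c_m^x c_m^y) / sqrt((c_m^x^2 + s_x^2)(c_m^y^2 + s_y^2));
# choosing c^2/(c^2 + s^2) = rho on BOTH sides makes it exactly rho, so
# c = s * sqrt(rho / (1 - rho)).
latent_weights <- function(config) {
  spec <- config$latent_spec
  k <- length(spec)
  dims <- c(pa = config$n_pa, fc = config$n_fc, gmv = config$n_gmv)
  out <- list()
  for (blk in c("pa", "fc", "gmv")) {
    d <- dims[[blk]]
    if (k == 0L) {
      out[[blk]] <- matrix(0, d, 0L)
      next
    }
    U <- matrix(0, d, k)
    for (m in seq_len(k)) {
      w <- spec[[m]][[paste0("w_", blk)]]
      if (is.null(w)) w <- rnorm(d)
      # Gram-Schmidt against earlier modes: orthogonal directions keep the
      # planted modes separable in closed form
      if (m > 1L) {
        w <- w - U[, seq_len(m - 1L), drop = FALSE] %*%
          crossprod(U[, seq_len(m - 1L), drop = FALSE], w)
      }
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) {
        stop("latent directions are collinear within a block", call. = FALSE)
      }
      U[, m] <- w / nw
    }
    s <- config$noise_scales[[blk]]
    cm <- vapply(spec, function(mm) s * sqrt(mm$rho / (1 - mm$rho)), 0)
    out[[blk]] <- sweep(U, 2L, cm, "*")
  }
  out
}

#' Population canonical correlations implied by a cohort config
#'
#' Closed-form canonical correlations of the residualized PA block against
#' one imaging block under the config's factor model, computed the generic
#' way: form the implied within- and cross-block covariances and take the
#' singular values of the whitened cross-covariance.  Confounder effects
#' are excluded because residualization removes them exactly (confounders
#' are generated independently of the latents).
#'
#' @param config a [cohort_config()].
#' @param block which imaging block to pair with PA: `"fc"` or `"gmv"`.
#'   For GMV the value refers to the Gaussian field before exponentiation,
#'   so the observed-scale correlation is approximate (close for small
#'   `gmv_scale`).
#' @return numeric vector of length `min(n_pa, q)` of population canonical
#'   correlations, descending.
#' @export
population_canonical_correlations <- function(config, block = c("fc", "gmv")) {
  stopifnot(inherits(config, "cohort_config"))
  block <- match.arg(block)
  W <- with_seed(config$seed, latent_weights(config))
  Wx <- W$pa
  Wy <- W[[block]]
  p <- config$n_pa
  q <- if (block == "fc") config$n_fc else config$n_gmv
  k <- min(p, q)
  if (ncol(Wx) == 0L) return(rep(0, k))
  # the extra within-PA collinearity factor is orthogonalized against the
  # planted directions at generation time, so it only adds variance in the
  # orthogonal complement and cannot change the singular values below;
  # include it anyway for a faithful implied covariance
  v <- with_seed(config$seed + 1L, pa_collinearity_direction(config, Wx))
  Sxx <- tcrossprod(Wx) + tcrossprod(v) + diag(config$noise_scales[["pa"]]^2, p)
  Syy <- tcrossprod(Wy) + diag(config$noise_scales[[block]]^2, q)
  Sxy <- Wx %*% t(Wy)
  if (min(eigen(Sxx, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("implied covariance is singular", call. = FALSE)
  }
  Kx <- pinv_sqrt(Sxx)$half
  Ky <- pinv_sqrt(Syy)$half
  sv <- svd(crossprod(Kx, Sxy) %*% Ky)$d
  rho <- sort(pmin(pmax(sv, 0), 1), decreasing = TRUE)
  c(rho, rep(0, k - length(rho)))[seq_len(k)]
}

# direction of the extra multicollinearity factor within PA, orthogonal to
# the planted cross-block directions (length = loading magnitude)
pa_collinearity_direction <- function(config, Wx) {
  p <- config$n_pa
  if (config$pa_collinearity <= 0) return(rep(0, p))
  v <- rnorm(p)
  if (ncol(Wx) > 0L) {
    U <- qr.Q(qr(Wx))
    v <- v - U %*% crossprod(U, v)
  }
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(rep(0, p))
  v / nv * config$pa_collinearity
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from the factor model described in
#' [cohort_config()]: confounders (one binary, the rest continuous), PA
#' features on realistic scales, Fisher-z FC edges consistent with
#' symmetric netmats with entries in (-1, 1), strictly positive regional
#' volumes, and binary disease labels from logistic models whose
#' intercepts are solved numerically to hit the configured prevalences.
#' The output is a deterministic function of the config (including its
#' seed).
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: a list with elements
#'   `confounders` (data.frame), `pa` (n x n_pa matrix, canonical column
#'   names), `fc_edges` (n x n_fc matrix of Fisher-z edges), `gmv`
#'   (n x n_gmv positive matrix), `disease` (n x diseases 0/1 matrix),
#'   `netmats` (list of symmetric matrices if `keep_netmats`, else NULL),
#'   `ground_truth` (population canonical correlations per imaging block,
#'   disease intercepts/coefficients), and `config`.
#' @examples
#' cfg <- cohort_config(200, n_fc_nodes = 8, n_gmv = 5, seed = 42)
#' coh <- generate_cohort(cfg)
#' dim(coh$fc_edges)  # 200 x 28
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  with_seed(config$seed, {
    W <- latent_weights(config)
    v_pa <- with_seed(config$seed + 1L, pa_collinearity_direction(config, W$pa))
    k <- length(config$latent_spec)

    # confounders: binary sex-like + continuous age-like / motion-like
    G <- matrix(rnorm(n * config$n_confounders), n, config$n_confounders)
    G[, 1L] <- rbinom(n, 1L, 0.5)
    colnames(G) <- c("sex", "age", paste0("motion", seq_len(max(0, config$n_confounders - 2L))))[
      seq_len(config$n_confounders)]

    # shared latents and the within-PA collinearity factor
    f <- matrix(rnorm(n * k), n, k)
    g_pa <- rnorm(n)

    # seed-determined confounder effect matrices per block
    conf_eff <- function(d) {
      config$confounder_strength *
        matrix(rnorm(config$n_confounders * d), config$n_confounders, d)
    }

    z_block <- function(blk, d) {
      Z <- matrix(rnorm(n * d, sd = config$noise_scales[[blk]]), n, d)
      if (k > 0L) Z <- Z + f %*% t(W[[blk]])
      Z + G %*% conf_eff(d)
    }

    z_pa <- z_block("pa", config$n_pa) + tcrossprod(g_pa, v_pa)
    z_fc <- z_block("fc", config$n_fc)
    z_gmv <- z_block("gmv", config$n_gmv)

    # PA features on plausible marginal scales (affine per column: canonical
    # correlations are unaffected)
    marg <- pa_marginals(config$n_pa)
    z_std <- scale(z_pa)
    attr(z_std, "scaled:center") <- attr(z_std, "scaled:scale") <- NULL
    pa <- sweep(sweep(z_std, 2L, marg$sigma, "*"), 2L, marg$mu, "+")
    colnames(pa) <- marg$names

    # FC edges: fixed scalar shrink on the Fisher-z scale, clamped at
    # atanh(0.95) (a many-sigma event) so netmat entries stay in (-0.95, 0.95)
    zmax <- atanh(0.95)
    fc_edges <- pmin(pmax(config$fc_edge_scale * z_fc, -zmax), zmax)
    colnames(fc_edges) <- sprintf("edge%04d", seq_len(config$n_fc))

    # strictly positive volumes via exponentiation of a small-scale field
    gmv <- exp(1 + config$gmv_scale * z_gmv)
    colnames(gmv) <- sprintf("roi%03d", seq_len(config$n_gmv))

    # disease labels: logistic in standardized confounders + PA (+ FC edges
    # through a rank-1 summary when beta_idp is a scalar strength)
    Gs <- standardize_cols(G)
    PAs <- standardize_cols(pa)
    diseases <- names(config$disease_spec)
    ylab <- matrix(0L, n, length(diseases), dimnames = list(NULL, diseases))
    truth_dis <- list()
    for (d in diseases) {
      ds <- config$disease_spec[[d]]
      b_conf <- rep_len(ds$beta_conf %||% 0, config$n_confounders)
      b_pa <- rep_len(ds$beta_pa %||% 0, config$n_pa)
      lp <- as.vector(Gs %*% b_conf + PAs %*% b_pa)
      b_idp <- ds$beta_idp %||% 0
      if (length(b_idp) == 1L && b_idp != 0) {
        # rank-1 imaging contribution along the primary planted direction
        dir_fc <- if (k > 0L) W$fc[, 1L] / sqrt(sum(W$fc[, 1L]^2)) else
          rep(1 / sqrt(config$n_fc), config$n_fc)
        idp_score <- as.vector(z_fc %*% dir_fc)
        lp <- lp + b_idp * idp_score / sd(idp_score)
      } else if (length(b_idp) == config$n_fc) {
        lp <- lp + as.vector(standardize_cols(fc_edges) %*% b_idp)
      }
      gen <- generate_disease(lp, prevalence = ds$prevalence,
                              seed = child_seed())
      ylab[, d] <- gen$labels
      truth_dis[[d]] <- list(intercept = gen$intercept,
                             beta_conf = b_conf, beta_pa = b_pa,
                             beta_idp = b_idp, prevalence = ds$prevalence)
    }

    netmats <- NULL
    if (config$keep_netmats) {
      netmats <- lapply(seq_len(n), function(i)
        unvectorize_netmat(fc_edges[i, ], config$n_fc_nodes))
    }

    structure(
      list(confounders = as.data.frame(G),
           pa = pa, fc_edges = fc_edges, gmv = gmv,
           disease = ylab, netmats = netmats,
           ground_truth = list(
             rho_fc = population_canonical_correlations(config, "fc"),
             rho_gmv = population_canonical_correlations(config, "gmv"),
             disease = truth_dis),
           config = config),
      class = "synthetic_cohort"
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rebuild one participant's netmat from stored FC edges
#'
#' @param cohort a `synthetic_cohort`.
#' @param i participant index.
#' @return symmetric `n_fc_nodes` x `n_fc_nodes` matrix with unit diagonal.
#' @export
cohort_netmat <- function(cohort, i) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  unvectorize_netmat(cohort$fc_edges[i, ], cohort$config$n_fc_nodes)
}

#' Draw binary disease labels from a logistic model
#'
#' Given a linear predictor (without intercept), draws Bernoulli labels
#' with `P(y = 1) = plogis(intercept + lp)`.  When `intercept` is omitted
#' it is solved numerically (by root-finding on the mean of `plogis`) so
#' the analytic prevalence over the supplied cohort equals `prevalence` —
#' the route by which rare outcomes are planted at a controlled rate.
#'
#' @param linear_predictor numeric vector (finite).
#' @param intercept log-odds intercept; mutually exclusive with
#'   `prevalence`.
#' @param prevalence target analytic prevalence in (0,1).
#' @param seed integer seed for the Bernoulli draws.
#' @return list with `labels` (0/1 integer vector), `intercept` used, and
#'   `analytic_prevalence` (mean of the fitted probabilities).
#' @export
generate_disease <- function(linear_predictor, intercept = NULL,
                             prevalence = NULL, seed = 1L) {
  lp <- as.numeric(linear_predictor)
  if (any(!is.finite(lp))) stop("linear predictor contains non-finite values", call. = FALSE)
  if (is.null(intercept)) {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1) {
      config_error("prevalence", "must lie in (0, 1) when intercept is not given")
    }
    intercept <- uniroot(function(b0) mean(plogis(b0 + lp)) - prevalence,
                         lower = -40, upper = 40, tol = 1e-10)$root
  }
  pr <- plogis(intercept + lp)
  labels <- with_seed(seed, rbinom(length(lp), 1L, pr))
  list(labels = as.integer(labels), intercept = intercept,
       analytic_prevalence = mean(pr))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic cohort: %d participants\n", cfg$n_participants))
  cat(sprintf("  PA features : %d\n", cfg$n_pa))
  cat(sprintf("  FC edges    : %d (%d-node netmats)\n", cfg$n_fc, cfg$n_fc_nodes))
  cat(sprintf("  GMV regions : %d\n", cfg$n_gmv))
  cat(sprintf("  confounders : %s\n", paste(colnames(x$confounders), collapse = ", ")))
  if (length(cfg$latent_spec)) {
    cat(sprintf("  planted canonical correlations (PA-FC): %s\n",
                paste(format(x$ground_truth$rho_fc[seq_along(cfg$latent_spec)],
                             digits = 3), collapse = ", ")))
  } else {
    cat("  no planted shared structure\n")
  }
  prev <- colMeans(x$disease)
  cat(sprintf("  disease prevalence: %s\n",
              paste(sprintf("%s %.1f%%", names(prev), 100 * prev), collapse = ", ")))
  invisible(x)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Cohort config: n=%d, PA=%d, FC nodes=%d (%d edges), GMV=%d, seed=%d\n",
              x$n_participants, x$n_pa, x$n_fc_nodes, x$n_fc, x$n_gmv, x$seed))
  cat(sprintf("  planted modes: %d%s\n", length(x$latent_spec),
              if (length(x$latent_spec))
                sprintf(" (rho: %s)", paste(vapply(x$latent_spec, `[[`, 0, "rho"),
                                            collapse = ", ")) else ""))
  invisible(x)
}
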