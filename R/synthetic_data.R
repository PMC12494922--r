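#' Structural connectome container
#'
#' Nonnegative symmetric coupling weights with 3-D region coordinates, a hub
#' mask, and region labels. Stands in for a diffusion-imaging connectome.
#'
#' @param weights Nonnegative symmetric matrix with zero diagonal.
#' @param coordinates `n x 3` matrix of region positions (mm-like units).
#' @param hub_mask Logical vector flagging hub regions (at least one).
#' @param region_labels Optional character vector.
#' @return An object of class `structural_connectome`.
#' @export
structural_connectome <- function(weights, coordinates, hub_mask,
                                  region_labels = NULL) {
  check_symmetric(weights, "connectome weights")
  n <- nrow(weights)
  stopifnot(all(weights >= 0), all(diag(weights) == 0),
            is.matrix(coordinates), nrow(coordinates) == n,
            ncol(coordinates) == 3, all(is.finite(coordinates)),
            is.logical(hub_mask), length(hub_mask) == n, any(hub_mask))
  if (is.null(region_labels)) region_labels <- default_region_labels(n)
  structure(
    list(weights = weights, coordinates = coordinates,
         hub_mask = hub_mask, region_labels = region_labels),
    class = "structural_connectome"
  )
}

#' Generate a hub-structured random structural connectome
#'
#' Builds a connected weighted graph whose hub regions (a spatially
#' contiguous cluster in coordinate space) carry systematically stronger
#' connections, emulating a frontoparietal hub system. The edge count is
#' exactly `round(density * n(n-1)/2)`; a random spanning tree guarantees
#' connectedness; remaining edges preferentially attach to hubs.
#'
#' @param n_regions Number of regions (default 78, a cortical parcellation).
#' @param hub_fraction Fraction of regions designated hubs, in `(0, 1)`.
#' @param density Fraction of possible edges present, in `(0, 1]`.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A [structural_connectome()].
#' @export
generate_structural_connectome <- function(n_regions = 78, hub_fraction = 0.2,
                                           density = 0.3, seed = 1) {
  stopifnot(n_regions >= 2, hub_fraction > 0, hub_fraction < 1,
            density > 0, density <= 1)
  n_edges_total <- n_regions * (n_regions - 1) / 2
  m <- floor(density * n_edges_total + 0.5)
  if (m < n_regions - 1) {
    stop("density too low to permit a connected graph", call. = FALSE)
  }
  n_hub <- max(1L, as.integer(round(hub_fraction * n_regions)))
  with_local_seed(seed, {
    hub_mask <- rep(FALSE, n_regions)
    hub_mask[seq_len(n_hub)] <- TRUE
    # hubs form one spatial cluster; the rest spread through a 100 mm cube
    coords <- matrix(stats::runif(n_regions * 3, 0, 100), n_regions, 3)
    hub_center <- c(50, 75, 60)
    coords[hub_mask, ] <- matrix(rep(hub_center, each = n_hub), n_hub, 3) +
      matrix(stats::rnorm(n_hub * 3, 0, 8), n_hub, 3)
    # random spanning tree (random permutation, attach each to an earlier node)
    perm <- sample.int(n_regions)
    edge_i <- integer(m)
    edge_j <- integer(m)
    for (k in 2:n_regions) {
      a <- perm[k]
      b <- perm[sample.int(k - 1, 1)]
      edge_i[k - 1] <- min(a, b)
      edge_j[k - 1] <- max(a, b)
    }
    n_tree <- n_regions - 1
    # candidate non-tree edges, hub-incident pairs preferred
    all_pairs <- which(upper.tri(matrix(0, n_regions, n_regions)))
    tree_lin <- (edge_j[1:n_tree] - 1) * n_regions + edge_i[1:n_tree]
    cand <- setdiff(all_pairs, tree_lin)
    ci <- ((cand - 1) %% n_regions) + 1
    cj <- ((cand - 1) %/% n_regions) + 1
    n_hub_end <- hub_mask[ci] + hub_mask[cj]
    prob <- c(1, 4, 8)[n_hub_end + 1]
    extra <- m - n_tree
    if (extra > 0) {
      pick <- sample.int(length(cand), extra, prob = prob)
      edge_i[(n_tree + 1):m] <- ci[pick]
      edge_j[(n_tree + 1):m] <- cj[pick]
    }
    hub_end <- hub_mask[edge_i] + hub_mask[edge_j]
    w <- stats::rlnorm(m, meanlog = 0, sdlog = 0.4) * c(1, 1.6, 2.4)[hub_end + 1]
    weights <- matrix(0, n_regions, n_regions)
    weights[cbind(edge_i, edge_j)] <- w
    weights <- weights + t(weights)
    structural_connectome(weights, coords, hub_mask)
  })
}

#' Cohort specification
#'
#' Defines the study conditions a synthetic cohort is drawn under: group
#' sizes, age range, expertise distribution and units, and the latent
#' coupling model `g(subject) = g0 - g_age * (age - age_min) /
#' (age_max - age_min) + g_exp * z(expertise) + coupling noise`, from which
#' each subject's connectivity matrix is predicted with the linearized Hopf
#' model.
#'
#' @param n_per_group Subjects per group (default 30).
#' @param age_range Two ages in years, within `[17, 91]`.
#' @param domain One of `"dance"`, `"music"`, `"visual"`, `"gaming"`,
#'   `"learning"`.
#' @param paired If `TRUE`, a within-subject pre/post design (groups `pre`
#'   and `post`, shared subject noise); otherwise expert vs non_expert.
#' @param g0 Baseline coupling (default 0.6).
#' @param g_age Age-related coupling decline across the age range
#'   (default 0.3).
#' @param g_exp Expertise-related coupling gain per expertise z-score
#'   (default 0.08).
#' @param coupling_noise_sd Between-subject sd of the latent coupling
#'   (default 0.02).
#' @param obs_noise_sd Measurement noise sd, applied on the Fisher-z scale
#'   of the off-diagonal correlations (default 0.05).
#' @param a,f,beta Hopf parameters of the generative model; `a` must be
#'   negative (noise-driven regime) for the linear prediction to hold.
#' @param full_simulation If `TRUE`, matrices come from stochastic
#'   integration of the full nonlinear system instead of the linear
#'   prediction (slower; used for end-to-end time-series checks).
#' @param sim_duration Seconds of simulation when `full_simulation = TRUE`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 30, age_range = c(20, 80),
                        domain = c("music", "dance", "visual", "gaming",
                                   "learning"),
                        paired = FALSE, g0 = 0.6, g_age = 0.3, g_exp = 0.08,
                        coupling_noise_sd = 0.02, obs_noise_sd = 0.05,
                        a = -0.05, f = 10, beta = 0.1,
                        full_simulation = FALSE, sim_duration = 30) {
  domain <- match.arg(domain)
  stopifnot(n_per_group >= 2, length(age_range) == 2,
            age_range[1] >= 17, age_range[2] <= 91,
            age_range[1] < age_range[2],
            coupling_noise_sd >= 0, obs_noise_sd >= 0)
  structure(
    list(n_per_group = n_per_group, age_range = age_range, domain = domain,
         paired = paired, g0 = g0, g_age = g_age, g_exp = g_exp,
         coupling_noise_sd = coupling_noise_sd, obs_noise_sd = obs_noise_sd,
         a = a, f = f, beta = beta, full_simulation = full_simulation,
         sim_duration = sim_duration),
    class = "cohort_spec"
  )
}

# expertise score draws in domain-specific units; non-experts/pre sit near 0
expertise_draw <- function(domain, group, n) {
  scale <- switch(domain,
    dance = 55,      # months of formal instruction
    music = 13,      # years of experience
    visual = 4.5,    # years of art education
    gaming = 18,     # hours per week
    learning = 10    # actions-per-minute gain
  )
  hi <- group %in% c("expert", "post")
  mu <- ifelse(hi, scale, scale * 0.05)
  pmax(stats::rnorm(n, mu, mu * 0.35 + 0.01), 0)
}

#' Generate a synthetic cohort of connectivity matrices
#'
#' Draws subjects (ages uniform over the configured range, domain-specific
#' expertise scores) and produces one connectivity matrix per subject from
#' the Hopf model at that subject's latent coupling. Expertise increases
#' coupling (hence hub connectivity) when `g_exp > 0`; age decreases it when
#' `g_age > 0`. Measurement noise is added on the Fisher-z scale and
#' back-transformed so entries stay in `[-1, 1]`. Paired designs reuse each
#' subject's measurement-noise draw pre and post.
#'
#' @param spec A [cohort_spec()].
#' @param connectome A [structural_connectome()].
#' @param seed Integer master seed.
#' @return An object of class `cohort`: list with `subjects` (data frame),
#'   `matrices` (list of [fc_matrix()]), and `provenance`.
#' @export
generate_cohort <- function(spec, connectome, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(connectome, "structural_connectome"))
  groups <- if (spec$paired) c("pre", "post") else c("expert", "non_expert")
  n <- spec$n_per_group
  with_local_seed(seed, {
    if (spec$paired) {
      base_age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
      age <- rep(base_age, 2)
      id <- rep(sprintf("S%03d", seq_len(n)), 2)
      group <- rep(groups, each = n)
    } else {
      age <- stats::runif(2 * n, spec$age_range[1], spec$age_range[2])
      id <- sprintf("S%03d", seq_len(2 * n))
      group <- rep(groups, each = n)
    }
    n_tot <- length(id)
    sex <- sample(c("F", "M"), n_tot, replace = TRUE)
    if (spec$paired) sex[(n + 1):(2 * n)] <- sex[1:n]
    education <- pmin(pmax(round(stats::rnorm(n_tot, 15, 3)), 6), 22)
    if (spec$paired) education[(n + 1):(2 * n)] <- education[1:n]
    expertise <- expertise_draw(spec$domain, group, n_tot)
    subj_seed <- floor(child_seed(seed, seq_len(n_tot)))
    if (spec$paired) subj_seed[(n + 1):(2 * n)] <- subj_seed[1:n]
    z_exp <- as.numeric(scale(expertise))
    age_rel <- (age - spec$age_range[1]) / diff(spec$age_range)
    g <- spec$g0 - spec$g_age * age_rel + spec$g_exp * z_exp +
      stats::rnorm(n_tot, 0, spec$coupling_noise_sd)
    if (spec$paired) {
      # paired subjects share their coupling noise through the shared seed;
      # redraw g with a common subject-level perturbation
      eps <- stats::rnorm(n, 0, spec$coupling_noise_sd)
      g <- spec$g0 - spec$g_age * age_rel + spec$g_exp * z_exp + rep(eps, 2)
    }
    subjects <- data.frame(
      id = id, age = age, sex = sex, education_years = education,
      domain = spec$domain, group = group, expertise_score = expertise,
      coupling = g, seed = subj_seed, stringsAsFactors = FALSE
    )
    matrices <- vector("list", n_tot)
    for (i in seq_len(n_tot)) {
      p <- hopf_params(a = spec$a, f = spec$f, beta = spec$beta, G = g[i],
                       duration = spec$sim_duration, seed = subj_seed[i])
      fc <- tryCatch({
        if (spec$full_simulation) {
          compute_fc(simulate_hopf(connectome, p))
        } else {
          linear_fc(connectome, p)
        }
      }, error = function(e) {
        stop(sprintf("subject %s: %s", id[i], conditionMessage(e)),
             call. = FALSE)
      })
      if (spec$obs_noise_sd > 0) {
        v <- fc$values
        nn <- nrow(v)
        ut <- upper_tri_index(nn)
        noise_seed <- floor(child_seed(subj_seed[i], 7))
        eps <- with_local_seed(noise_seed,
                               stats::rnorm(length(ut), 0, spec$obs_noise_sd))
        z <- fisher_z(v[ut]) + eps
        v[ut] <- fisher_z_inv(z)
        v[lower.tri(v)] <- t(v)[lower.tri(v)]
        diag(v) <- 1
        fc <- fc_matrix(v, "correlation", fc$region_labels)
      }
      matrices[[i]] <- fc
    }
    structure(
      list(subjects = subjects, matrices = matrices,
           provenance = list(spec = spec, seed = seed,
                             n_regions = nrow(connectome$weights))),
      class = "cohort"
    )
  })
}

#' Generate spatially autocorrelated synthetic term maps
#'
#' Stand-ins for meta-analytic cognitive term association maps: Gaussian
#' random fields over the connectome coordinates, smoothed with a Gaussian
#' distance kernel at the given length-scale and standardized to zero mean,
#' unit variance.
#'
#' @param n_terms Number of maps (the full meta-analytic set uses 89).
#' @param connectome A [structural_connectome()] supplying coordinates.
#' @param smoothness Spatial length-scale (same units as coordinates);
#'   as it approaches 0 the maps approach i.i.d. noise.
#' @param seed Integer seed.
#' @return List of [regional_map()] objects named `term_01`, ...
#' @export
generate_term_maps <- function(n_terms = 89, connectome, smoothness = 20,
                               seed = 1) {
  stopifnot(n_terms >= 1, inherits(connectome, "structural_connectome"))
  if (smoothness <= 0) stop("smoothness must be positive")
  D <- as.matrix(stats::dist(connectome$coordinates))
  K <- exp(-D^2 / (2 * smoothness^2))
  K <- K / rowSums(K)
  n <- nrow(D)
  with_local_seed(seed, {
    lapply(seq_len(n_terms), function(t) {
      z <- as.vector(K %*% stats::rnorm(n))
      z <- (z - mean(z)) / stats::sd(z)
      regional_map(z, sprintf("term_%02d", t), connectome$region_labels)
    })
  })
}

#' Group sizes and age structure of the creative-expertise study arms
#'
#' Returns the per-domain design used by the analysis scripts: expert and
#' non-expert group sizes and approximate age ranges for tango dancing,
#' music, visual art and gaming, plus the pre/post learning arm.
#'
#' @return A data frame with columns `domain`, `n_per_group`, `age_min`,
#'   `age_max`, `paired`.
#' @export
default_study_design <- function() {
  data.frame(
    domain = c("dance", "music", "visual", "gaming", "learning"),
    n_per_group = c(23, 29, 15, 31, 24),
    age_min = c(22, 20, 20, 18, 19),
    age_max = c(42, 43, 38, 33, 32),
    paired = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}
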