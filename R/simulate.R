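#' Forward Wright-Fisher simulation parameters
#'
#' Discrete-generation forward simulation of 1-5 constant-size diploid
#' populations related by a caterpillar topology: `populations[1]` is the
#' trunk lineage and `split_times[i]` (generations before present, ordered
#' oldest first) is when `populations[n - i + 1]` splits off the trunk as a
#' copy of it. An outgroup is simply the population with the oldest split.
#' Default rates are desk-scale rescaled values: at `N = 200` they emulate
#' a large-`Ne` perennial cohort with the per-generation products `4*N*mu`
#' and `4*N*rho` held realistic.
#'
#' @param L Sequence length, bp.
#' @param N Diploid population size; scalar or named per-population vector.
#' @param mu Per-bp per-generation mutation rate (infinite-sites, uniform
#'   continuous positions).
#' @param rho Per-bp per-generation crossover rate.
#' @param populations Character vector of population labels (1-5), trunk
#'   first.
#' @param split_times Numeric vector, `length(populations) - 1` split times
#'   in generations before present, strictly decreasing (oldest first).
#' @param sample_sizes Diploids sampled per population at the end; scalar
#'   or named vector.
#' @param pulse Optional one-generation introgression pulse:
#'   `list(source=, target=, fraction=, time=)` (time in generations before
#'   present). Each target parent is drawn from the source with probability
#'   `fraction` in that generation.
#' @param sweep Optional hard sweep: `list(pop=, position=, s=, start=,
#'   require_fixation=)`. A single beneficial copy is injected at `start`
#'   generations before present; diploid fitness is additive
#'   (1, 1+s, 1+2s). With `require_fixation` the run restarts from the
#'   injection snapshot whenever the allele is lost (or is still
#'   segregating at sampling time), up to `retry_budget` restarts.
#' @param burn_in Burn-in generations before the oldest split (default
#'   `8 * N` of the trunk).
#' @param retry_budget Restart budget for `require_fixation` (default 100).
#' @param seed Master RNG seed; all draws derive from it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(L = 1e6, N = 200, mu = 1.5e-7, rho = 5e-7,
                       populations = c("A", "B"), split_times = 250,
                       sample_sizes = 20, pulse = NULL, sweep = NULL,
                       burn_in = NULL, retry_budget = 100, seed = 1) {
  n_pop <- length(populations)
  stopifnot(n_pop >= 1, n_pop <= 5, L > 0, mu >= 0, rho >= 0)
  if (length(split_times) != max(n_pop - 1, 0)) {
    abort("`split_times` must have one entry per non-trunk population")
  }
  if (length(split_times) > 1 && any(diff(split_times) >= 0)) {
    abort("`split_times` must be strictly decreasing (oldest first)")
  }
  N <- expand_per_pop(N, populations)
  sample_sizes <- expand_per_pop(sample_sizes, populations)
  if (!is.null(pulse)) {
    stopifnot(pulse$fraction >= 0, pulse$fraction <= 1,
              pulse$source %in% populations, pulse$target %in% populations)
  }
  if (!is.null(sweep)) {
    stopifnot(sweep$s > 0, sweep$pop %in% populations,
              sweep$position > 0, sweep$position <= L)
    sweep$require_fixation <- isTRUE(sweep$require_fixation)
  }
  burn_in <- burn_in %||% (8 * N[[populations[1]]])
  total_units <- sum(unlist(N)) * 2 * (burn_in + max(split_times, 0)) *
    (mu * L + rho * L + 1)
  if (total_units > 1e10) {
    warn("very large simulation (guard: N * L * generations); expect long runtimes")
  }
  structure(list(L = L, N = N, mu = mu, rho = rho,
                 populations = populations, split_times = split_times,
                 sample_sizes = sample_sizes, pulse = pulse, sweep = sweep,
                 burn_in = burn_in, retry_budget = retry_budget,
                 seed = as.integer(seed)),
            class = "sim_params")
}

expand_per_pop <- function(x, populations) {
  if (length(x) == 1 && is.null(names(x))) {
    x <- setNames(rep(x, length(populations)), populations)
  }
  if (!all(populations %in% names(x))) {
    abort("per-population values must be named for every population")
  }
  as.list(x[populations])
}

#' Run a forward Wright-Fisher simulation
#'
#' Each offspring haplotype is built by recombining the two haplotypes of a
#' sampled parent diploid (crossover count Poisson(`rho * L`), breakpoints
#' uniform), then new mutations arise at Poisson(`mu * L`) uniform
#' continuous positions per gamete (infinite sites; positions are rounded
#' to distinct integer bp only on output, with collisions re-drawn).
#' Splits copy the trunk population; a pulse redirects each target parent
#' to the source population with probability `fraction` for one
#' generation; a sweep injects one beneficial copy with additive fitness.
#' Sampled diploids are emitted as a phased [hap_data] with true ancestral
#' states (allele 0 is always ancestral), together with a ground-truth
#' list.
#'
#' Identical parameters and seed give byte-identical outputs.
#'
#' @param params A [sim_params()] object.
#' @param dir Optional output directory; when given, `sim.vcf`,
#'   `popmap.tsv` and `truth.txt` are written there.
#' @param contig Contig name for the emitted dataset.
#' @return A list with elements `data` ([hap_data]), `truth` (list) and
#'   `files` (paths or `NULL`).
#' @export
simulate_cohort <- function(params, dir = NULL, contig = "chr1") {
  stopifnot(inherits(params, "sim_params"))
  out <- with_seed(params$seed, sim_run(params, contig))
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(vcf = file.path(dir, "sim.vcf"),
                  popmap = file.path(dir, "popmap.tsv"),
                  truth = file.path(dir, "truth.txt"))
    write_vcf(out$data, files$vcf)
    write_popmap(out$data, files$popmap)
    write_sim_truth(out$truth, files$truth)
  }
  out$files <- files
  out
}

sim_run <- function(params, contig) {
  L <- params$L
  trunk <- params$populations[1]
  n_pop <- length(params$populations)
  # split schedule: populations[n - i + 1] splits at split_times[i]
  split_of <- setNames(rep(NA_real_, n_pop), params$populations)
  if (n_pop > 1) {
    split_of[params$populations[seq(n_pop, 2)]] <- params$split_times
  }
  state <- list(
    pops = setNames(list(matrix(0L, 2 * params$N[[trunk]], 0)), trunk),
    pos = numeric(0))
  sweep <- params$sweep
  swp <- list(status = "none", freq = NA_real_, attempts = 0L)
  pulse_realized <- NA_real_

  # burn-in: trunk alone
  for (g in seq_len(params$burn_in)) {
    state <- sim_generation(state, params, pulse_now = FALSE, sweep_col = NULL)
    state <- prune_fixed(state, lazy = TRUE)
  }
  state <- prune_fixed(state)

  tau_start <- if (n_pop > 1) max(params$split_times) else 0
  run_span <- function(state, tau_from, tau_to, sweep_active) {
    # generations at tau = tau_from-1, ..., tau_to (0 = present)
    res <- list(state = state, lost = FALSE, pulse_realized = NA_real_)
    tau <- tau_from
    while (tau > tau_to) {
      tau <- tau - 1
      for (p in names(split_of)[!is.na(split_of)]) {
        if (split_of[[p]] == tau + 1 && !p %in% names(res$state$pops)) {
          res$state$pops[[p]] <- res$state$pops[[trunk]]
        }
      }
      pulse_now <- !is.null(params$pulse) && params$pulse$time == tau + 1
      sweep_col <- NULL
      if (sweep_active) {
        sweep_col <- match(sweep$position, res$state$pos)
        if (is.na(sweep_col)) abort("internal: lost track of sweep column")
      }
      res$state <- sim_generation(res$state, params, pulse_now = pulse_now,
                                  sweep_col = sweep_col)
      if (pulse_now) {
        res$pulse_realized <- attr(res$state, "pulse_realized")
      }
      if (sweep_active) {
        col <- match(sweep$position, res$state$pos)
        hp <- res$state$pops[[sweep$pop]]
        fr <- sum(hp[, col]) / nrow(hp)
        if (fr == 0) {
          res$lost <- TRUE
          return(res)
        }
        if (fr == 1) sweep_active <- FALSE  # fixed: drop fitness weighting
      }
      res$state <- prune_fixed(res$state, keep_pos = sweep$position,
                               lazy = TRUE)
    }
    res
  }

  if (is.null(sweep)) {
    res <- run_span(state, tau_start, 0, sweep_active = FALSE)
    state <- res$state
    if (!is.na(res$pulse_realized)) pulse_realized <- res$pulse_realized
  } else {
    res <- run_span(state, tau_start, sweep$start, sweep_active = FALSE)
    state <- res$state
    if (!is.na(res$pulse_realized)) pulse_realized <- res$pulse_realized
    if (!sweep$pop %in% names(state$pops)) {
      abort("sweep population does not exist at the sweep start time")
    }
    snapshot <- state
    repeat {
      st <- snapshot
      inj <- inject_sweep(st, sweep)
      res <- run_span(inj, sweep$start, 0, sweep_active = TRUE)
      hp <- res$state$pops[[sweep$pop]]
      col <- match(sweep$position, res$state$pos)
      fr <- if (is.na(col)) 0 else sum(hp[, col]) / nrow(hp)
      ok <- if (sweep$require_fixation) fr == 1 else fr > 0
      if (!res$lost && ok) {
        swp$status <- if (fr == 1) "fixed" else "segregating"
        swp$freq <- fr
        state <- res$state
        if (!is.na(res$pulse_realized)) pulse_realized <- res$pulse_realized
        break
      }
      swp$attempts <- swp$attempts + 1L
      if (swp$attempts >= params$retry_budget) {
        abort(sprintf("sweep did not %s within %d restarts",
                      if (sweep$require_fixation) "fix" else "establish",
                      params$retry_budget))
      }
    }
  }
  state <- prune_fixed(state, keep_pos = if (is.null(sweep)) NULL else
    sweep$position)

  emit_sample(state, params, contig, swp, pulse_realized)
}

inject_sweep <- function(state, sweep) {
  hp <- state$pops[[sweep$pop]]
  carrier <- sample.int(nrow(hp), 1)
  newcol <- matrix(0L, nrow(hp), 1)
  newcol[carrier, 1] <- 1L
  state$pops[[sweep$pop]] <- cbind(hp, newcol)
  for (p in setdiff(names(state$pops), sweep$pop)) {
    state$pops[[p]] <- cbind(state$pops[[p]],
                             matrix(0L, nrow(state$pops[[p]]), 1))
  }
  state$pos <- c(state$pos, sweep$position)
  state
}

# one generation for every current population, in creation order
sim_generation <- function(state, params, pulse_now, sweep_col) {
  L <- params$L
  pops <- names(state$pops)
  # 1. mutation draws, fixed order
  muts <- lapply(pops, function(p) {
    G <- nrow(state$pops[[p]])
    K <- rpois(1, G * params$mu * L)
    list(K = K, pos = runif(K, 0, L),
         gam = if (K > 0) sample.int(G, K, replace = TRUE) else integer(0))
  })
  names(muts) <- pops
  K_tot <- sum(vapply(muts, `[[`, numeric(1), "K"))
  offset <- c(0, cumsum(vapply(muts, `[[`, numeric(1), "K")))
  names(offset) <- c(pops, "..end")
  pulse_frac <- NA_real_
  new_pops <- state$pops
  for (pi in seq_along(pops)) {
    p <- pops[pi]
    H <- state$pops[[p]]
    N <- nrow(H) / 2
    G <- nrow(H)
    w <- NULL
    if (!is.null(sweep_col) && p == params$sweep$pop) {
      cnt <- H[seq(1, G, 2), sweep_col] + H[seq(2, G, 2), sweep_col]
      if (any(cnt > 0) && !all(cnt == 2)) w <- 1 + params$sweep$s * cnt
    }
    pd <- if (is.null(w)) sample.int(N, G, replace = TRUE) else
      sample.int(N, G, replace = TRUE, prob = w)
    Hpar <- H
    if (pulse_now && p == params$pulse$target) {
      # an exact fraction of parent draws is redirected to the source
      # population ("replaces fraction f of target parents")
      src <- state$pops[[params$pulse$source]]
      n_take <- round(params$pulse$fraction * G)
      take <- sample.int(G, n_take)
      pulse_frac <- n_take / G
      pd_src <- sample.int(nrow(src) / 2, G, replace = TRUE)
      Hpar <- rbind(H, src)
      pd[take] <- N + pd_src[take]
    }
    par <- cbind(2L * pd - 2L, 2L * pd - 1L)  # 0-based haplotype rows
    new_pops[[p]] <- cpp_make_gametes(
      Hpar, par, state$pos, params$rho, L,
      as.integer(K_tot),
      as.integer(muts[[p]]$gam - 1L),
      as.integer(offset[pi] + seq_len(muts[[p]]$K) - 1L))
  }
  out <- list(pops = new_pops,
              pos = c(state$pos, unlist(lapply(muts, `[[`, "pos"),
                                        use.names = FALSE)))
  if (pulse_now) attr(out, "pulse_realized") <- pulse_frac
  out
}

# drop columns fixed (0 or 1) across every population; with lazy = TRUE the
# (costly) matrix subset is deferred until enough dead columns accumulate
prune_fixed <- function(state, keep_pos = NULL, lazy = FALSE) {
  if (!length(state$pos)) return(state)
  tot1 <- Reduce(`+`, lapply(state$pops, colSums))
  rows <- sum(vapply(state$pops, nrow, numeric(1)))
  keep <- tot1 > 0 & tot1 < rows
  if (!is.null(keep_pos)) keep <- keep | state$pos %in% keep_pos
  n_drop <- sum(!keep)
  if (n_drop == 0 || (lazy && n_drop < 0.2 * length(keep))) return(state)
  state$pops <- lapply(state$pops, function(H) H[, keep, drop = FALSE])
  state$pos <- state$pos[keep]
  state
}

emit_sample <- function(state, params, contig, swp, pulse_realized) {
  L <- params$L
  pops <- params$populations[params$populations %in% names(state$pops)]
  rows_list <- list()
  ids <- character(0)
  pop_lab <- character(0)
  for (p in pops) {
    k <- params$sample_sizes[[p]]
    N <- nrow(state$pops[[p]]) / 2
    pick <- sort(sample.int(N, k))
    rows <- as.vector(rbind(2 * pick - 1, 2 * pick))
    rows_list[[p]] <- state$pops[[p]][rows, , drop = FALSE]
    ids <- c(ids, sprintf("%s_%02d", p, seq_len(k)))
    pop_lab <- c(pop_lab, rep(p, k))
  }
  H <- do.call(rbind, rows_list)
  cnt <- colSums(H)
  seg <- cnt > 0 & cnt < nrow(H)
  H <- H[, seg, drop = FALSE]
  pos <- state$pos[seg]
  bp <- floor(pos) + 1
  # infinite sites at VCF level: re-draw colliding integer positions
  while (anyDuplicated(bp) > 0) {
    dup <- which(duplicated(bp))
    bp[dup] <- sample.int(L, length(dup), replace = TRUE)
  }
  o <- order(bp)
  ds <- hap_data(contig = contig, positions = bp[o],
                 H = H[, o, drop = FALSE],
                 sample_ids = ids, pops = pop_lab,
                 ancestral = rep(0L, sum(seg)),
                 phased = TRUE, contig_length = L)
  pi_pop <- vapply(unique(pop_lab), function(p) {
    sum(site_pi_values(ds$H[pop_rows(ds, p), , drop = FALSE])) / L
  }, numeric(1))
  truth <- list(
    params = params,
    seed = params$seed,
    n_sites = n_sites(ds),
    sweep_status = swp$status,
    sweep_final_freq = swp$freq,
    sweep_position = if (is.null(params$sweep)) NA_real_ else
      params$sweep$position,
    sweep_restarts = swp$attempts,
    pulse_realized_fraction = pulse_realized,
    pi_per_pop = pi_pop,
    ancestral_allele = "REF")
  list(data = ds, truth = truth)
}

#' Write simulation ground truth as key-value text
#' @param truth Truth list from [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  p <- truth$params
  kv <- c(
    "truth_format_version: 1",
    sprintf("seed: %d", truth$seed),
    sprintf("L: %g", p$L),
    sprintf("mu: %g", p$mu),
    sprintf("rho: %g", p$rho),
    sprintf("populations: %s", paste(p$populations, collapse = ",")),
    sprintf("N: %s", paste(unlist(p$N), collapse = ",")),
    sprintf("split_times: %s", paste(p$split_times, collapse = ",")),
    sprintf("sample_sizes: %s", paste(unlist(p$sample_sizes), collapse = ",")),
    sprintf("burn_in: %g", p$burn_in),
    sprintf("n_sites: %d", truth$n_sites),
    sprintf("ancestral_allele: %s", truth$ancestral_allele),
    sprintf("sweep_pop: %s", if (is.null(p$sweep)) "NA" else p$sweep$pop),
    sprintf("sweep_position: %s", format(truth$sweep_position)),
    sprintf("sweep_s: %s", if (is.null(p$sweep)) "NA" else format(p$sweep$s)),
    sprintf("sweep_status: %s", truth$sweep_status),
    sprintf("sweep_final_freq: %s", format(truth$sweep_final_freq)),
    sprintf("sweep_restarts: %d", truth$sweep_restarts),
    sprintf("pulse: %s", if (is.null(p$pulse)) "NA" else
      sprintf("%s->%s f=%g t=%g", p$pulse$source, p$pulse$target,
              p$pulse$fraction, p$pulse$time)),
    sprintf("pulse_realized_fraction: %s", format(truth$pulse_realized_fraction)),
    sprintf("pi_per_pop: %s",
            paste(sprintf("%s=%.8g", names(truth$pi_per_pop),
                          truth$pi_per_pop), collapse = ",")))
  writeLines(kv, path)
  invisible(path)
}

#' Implant a divergence-plus-diversity-loss segment
#'
#' Test fixture for the CDR scan: within the segment, population-A
#' haplotypes are collapsed towards a single template haplotype (diversity
#' loss) with per-entry probability `strength`, and a random fraction of
#' segment sites (`strength * fix_fraction`) is driven to a fixed
#' difference between the groups (differentiation gain). Deterministic
#' under `seed`; the truth interval is recorded in attribute
#' `"implant_truth"`.
#'
#' @param ds A [hap_data] holding both populations.
#' @param pop_a Population collapsed and fixed for the template allele.
#' @param pop_b Population fixed for the opposite allele at fixed-difference
#'   sites.
#' @param start,end Segment, 0-based half-open bp.
#' @param strength In `[0, 1]`; 0 leaves the data unchanged, 1 removes all
#'   `pop_a` diversity inside the segment.
#' @param fix_fraction Scales the fixed-difference site fraction.
#' @param seed RNG seed.
#' @return The modified [hap_data].
#' @export
implant_divergence_segment <- function(ds, pop_a, pop_b, start, end,
                                       strength = 0.95, fix_fraction = 0.3,
                                       seed = 1) {
  if (start < 0 || end > ds$contig_length || start >= end) {
    abort("segment outside the dataset's coordinate range")
  }
  stopifnot(strength >= 0, strength <= 1)
  sites <- which(ds$positions - 1 >= start & ds$positions - 1 < end)
  if (!length(sites)) return(ds)
  rows_a <- pop_rows(ds, pop_a)
  rows_b <- pop_rows(ds, pop_b)
  ds$H <- with_seed(as.integer(seed), {
    H <- ds$H
    template <- H[rows_a[1], sites]
    mask <- matrix(runif(length(rows_a) * length(sites)) < strength,
                   nrow = length(rows_a))
    block <- H[rows_a, sites, drop = FALSE]
    tmpl <- matrix(template, nrow = length(rows_a), ncol = length(sites),
                   byrow = TRUE)
    block[mask] <- tmpl[mask]
    H[rows_a, sites] <- block
    fix <- sites[runif(length(sites)) < strength * fix_fraction]
    if (length(fix)) {
      tf <- template[match(fix, sites)]
      H[rows_a, fix] <- matrix(tf, length(rows_a), length(fix), byrow = TRUE)
      H[rows_b, fix] <- matrix(1L - tf, length(rows_b), length(fix),
                               byrow = TRUE)
    }
    H
  })
  attr(ds, "implant_truth") <- list(start = start, end = end,
                                    strength = strength, seed = seed)
  ds
}
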