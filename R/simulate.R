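# Jukes-Cantor closed forms -------------------------------------------------

#' Expected proportion of differing sites under Jukes-Cantor divergence
#'
#' `jc_expected_p(d)` is the probability that a site differs between two
#' sequences separated by `d` expected substitutions per site under the
#' JC69 model: `(3/4)(1 - exp(-4d/3))`. `jc_divergence(p)` is its inverse,
#' defined for `p < 3/4`.
#'
#' @param d Expected substitutions per site (nonnegative).
#' @param p Expected proportion of differing sites, in `[0, 0.75)`.
#' @return Numeric vector.
#' @examples
#' jc_expected_p(0.1)              # ~0.0936
#' jc_divergence(jc_expected_p(0.15))
#' @export
jc_expected_p <- function(d) {
  if (any(d < 0)) stop("divergence d must be nonnegative", call. = FALSE)
  0.75 * (1 - exp(-4 * d / 3))
}

#' @rdname jc_expected_p
#' @export
jc_divergence <- function(p) {
  if (any(p < 0 | p >= 0.75)) {
    stop("p must lie in [0, 0.75) for the JC inverse", call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

# composition of per-site difference probabilities across two consecutive
# branches under JC: p1 (+) p2 = p1 + p2 - (4/3) p1 p2
.jc_compose <- function(p1, p2) p1 + p2 - (4 / 3) * p1 * p2

.stoch_round <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(length(x)) < (x - f)))
}

# substitute the given sites of a base vector to a uniformly chosen
# different base
.mutate_sites <- function(seq, sites) {
  for (s in sites) {
    seq[s] <- sample(setdiff(c("A", "C", "G", "T"), seq[s]), 1L)
  }
  seq
}

#' Evolve a sequence under the Jukes-Cantor model
#'
#' Evolves a gap-free ACGT sequence along a branch of `d` expected
#' substitutions per site. Each substituted site is replaced by a uniformly
#' chosen different base, so the per-site difference probability is
#' `jc_expected_p(d)` and compositions across consecutive branches follow
#' the JC closed form.
#'
#' Two sampling modes are offered. `"bernoulli"` substitutes every site
#' independently with probability `jc_expected_p(d)` — the literal
#' per-site process. `"exact"` (the default used by the simulator) draws
#' the number of substituted sites as the stochastically rounded
#' expectation `L * jc_expected_p(d)` and places them without replacement:
#' the per-site marginal is identical, but the realised divergence of a
#' branch concentrates on its expectation, so simulated datasets track
#' their configured divergence targets even at short alignments and small
#' sample sizes.
#'
#' @param seq Character vector (or single string) over A/C/G/T.
#' @param d Expected substitutions per site, nonnegative.
#' @param method `"exact"` or `"bernoulli"`.
#' @return Evolved sequence in the same form as the input.
#' @export
evolve_jc <- function(seq, d, method = c("exact", "bernoulli")) {
  method <- match.arg(method)
  as_string <- length(seq) == 1L && nchar(seq[1L]) > 1L
  s <- if (as_string) strsplit(seq, "", fixed = TRUE)[[1L]] else seq
  s <- .normalise_chars(s)
  if (!all(s %in% c("A", "C", "G", "T"))) {
    stop("evolve_jc requires a gap-free A/C/G/T sequence", call. = FALSE)
  }
  if (!is.numeric(d) || length(d) != 1L || d < 0) {
    stop("divergence d must be a single nonnegative number", call. = FALSE)
  }
  q <- jc_expected_p(d)
  L <- length(s)
  sites <- if (method == "bernoulli") {
    which(stats::runif(L) < q)
  } else {
    k <- min(.stoch_round(L * q), L)
    if (k) sample.int(L, k) else integer(0)
  }
  s <- .mutate_sites(s, sites)
  if (as_string) paste(s, collapse = "") else s
}

# Fixed four-group topology ------------------------------------------------

# tip roles on the fixed rooted shape (cristatus,(plumchrus,(flem_large,
# flem_small))); unrooted, the quartet separates {flem_large, flem_small}
# from {plumchrus, cristatus}
.SIM_ROLES <- c("cristatus", "plumchrus", "flem_large", "flem_small")

# Solve the five unrooted quartet edge lengths, in per-site difference
# probability units between group ancestors, from the six configured
# between-group expectations (already adjusted for within-group diversity).
# Errors name the violated additivity/nonnegativity condition.
.solve_quartet <- function(p_anc, tol = 1e-6) {
  g <- function(a, b) p_anc[a, b]
  four_pt <- (g("flem_large", "plumchrus") + g("flem_small", "cristatus")) -
             (g("flem_large", "cristatus") + g("flem_small", "plumchrus"))
  if (abs(four_pt) > tol) {
    stop(sprintf(paste0(
      "unrealizable divergences: additivity requires d(flem_large,plumchrus)",
      " + d(flem_small,cristatus) = d(flem_large,cristatus) +",
      " d(flem_small,plumchrus) (off by %.3g)"), four_pt), call. = FALSE)
  }
  tL <- (g("flem_large", "flem_small") + g("flem_large", "plumchrus") -
           g("flem_small", "plumchrus")) / 2
  tS <- g("flem_large", "flem_small") - tL
  tP <- (g("plumchrus", "cristatus") + g("flem_large", "plumchrus") -
           g("flem_large", "cristatus")) / 2
  tC <- g("plumchrus", "cristatus") - tP
  b  <- g("flem_large", "plumchrus") - tL - tP
  edges <- c(flem_large = tL, flem_small = tS, plumchrus = tP,
             cristatus = tC, internal = b)
  checks <- c(
    flem_large = "d(flem_large,flem_small) + d(flem_large,plumchrus) >= d(flem_small,plumchrus)",
    flem_small = "d(flem_large,flem_small) + d(flem_small,plumchrus) >= d(flem_large,plumchrus)",
    plumchrus  = "d(plumchrus,cristatus) + d(flem_large,plumchrus) >= d(flem_large,cristatus)",
    cristatus  = "d(plumchrus,cristatus) + d(flem_large,cristatus) >= d(flem_large,plumchrus)",
    internal   = "d(flem_large,flem_small) <= d(flem_*,plumchrus) (forms must be the shallowest split)")
  for (e in names(edges)) {
    if (edges[[e]] < -tol) {
      stop(sprintf("unrealizable divergences: violated %s (edge '%s' = %.3g)",
                   checks[[e]], e, edges[[e]]), call. = FALSE)
    }
  }
  pmax(edges, 0)
}

#' Build a multi-locus simulation configuration
#'
#' Defines the data-generating conditions for [simulate_dataset()]: four
#' groups on the fixed rooted topology
#' `(cristatus,(plumchrus,(flem_large, flem_small)))`, and per-locus
#' expected between-group divergences (uncorrected p units), within-group
#' diversities (expected substitutions/site) and IUPAC ambiguity injection
#' rates. Between-group expectations are converted to ancestor-to-ancestor
#' branch lengths at construction, after discounting the within-group
#' contribution through the JC composition rule; infeasible settings
#' (non-additive divergences, negative branches, between-group divergence
#' below the within-group diversity) fail here with a message naming the
#' violated condition.
#'
#' @param seed Integer RNG seed.
#' @param group_sizes Named integer vector over the roles `cristatus`,
#'   `plumchrus`, `flem_large`, `flem_small`.
#' @param locus_specs Named list; each element a list with `length`
#'   (alignment columns), `between_p` (symmetric 4x4 matrix over the roles,
#'   expected pairwise p between groups), `intra` (named per-role, or a
#'   single number: expected within-group substitutions/site) and
#'   `ambiguity_rate` (per-base probability of replacement by a two-fold
#'   IUPAC code).
#' @param species,forms Named character vectors over the roles giving the
#'   metadata labels to emit.
#' @return An object of class `sim_config` (with solved per-locus edge
#'   lengths in `$locus_specs[[...]]$edges_p`).
#' @export
simulation_config <- function(seed, group_sizes, locus_specs,
                              species = c(cristatus = "N. cristatus",
                                          plumchrus = "N. plumchrus",
                                          flem_large = "N. flemingeri",
                                          flem_small = "N. flemingeri"),
                              forms = c(cristatus = "", plumchrus = "",
                                        flem_large = "large",
                                        flem_small = "small")) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!all(.SIM_ROLES %in% names(group_sizes))) {
    stop(sprintf("group_sizes must name all roles: %s",
                 paste(.SIM_ROLES, collapse = ", ")), call. = FALSE)
  }
  group_sizes <- group_sizes[.SIM_ROLES]
  if (any(group_sizes < 1L)) stop("group sizes must be >= 1", call. = FALSE)
  if (is.null(names(locus_specs)) || any(names(locus_specs) == "")) {
    stop("locus_specs must be a named list", call. = FALSE)
  }
  for (nm in names(locus_specs)) {
    sp <- locus_specs[[nm]]
    if (is.null(sp$length) || sp$length < 1L) {
      stop(sprintf("locus '%s': length must be >= 1", nm), call. = FALSE)
    }
    if (is.null(sp$ambiguity_rate)) sp$ambiguity_rate <- 0
    if (sp$ambiguity_rate < 0 || sp$ambiguity_rate > 1) {
      stop(sprintf("locus '%s': ambiguity_rate must be in [0,1]", nm),
           call. = FALSE)
    }
    if (length(sp$intra) == 1L && is.null(names(sp$intra))) {
      sp$intra <- stats::setNames(rep(sp$intra, 4L), .SIM_ROLES)
    }
    sp$intra <- sp$intra[.SIM_ROLES]
    if (any(is.na(sp$intra)) || any(sp$intra < 0)) {
      stop(sprintf("locus '%s': intra diversities must be nonnegative and cover all roles", nm),
           call. = FALSE)
    }
    bp <- sp$between_p
    if (!is.matrix(bp) || !all(.SIM_ROLES %in% rownames(bp)) ||
        !all(.SIM_ROLES %in% colnames(bp))) {
      stop(sprintf("locus '%s': between_p must be a 4x4 matrix over the roles", nm),
           call. = FALSE)
    }
    bp <- bp[.SIM_ROLES, .SIM_ROLES]
    if (any(abs(bp - t(bp)) > 1e-12) || any(bp < 0)) {
      stop(sprintf("locus '%s': between_p must be symmetric and nonnegative", nm),
           call. = FALSE)
    }
    # per-specimen tip difference probability and pooled within-group term
    q <- jc_expected_p(sp$intra / 2)
    p_anc <- bp
    for (a in .SIM_ROLES) for (b in .SIM_ROLES) {
      if (a == b) { p_anc[a, b] <- 0; next }
      s <- .jc_compose(q[[a]], q[[b]])
      p_anc[a, b] <- (bp[a, b] - s) / (1 - (4 / 3) * s)
      if (p_anc[a, b] < -1e-9) {
        stop(sprintf(paste0(
          "unrealizable divergences at locus '%s': between-group p(%s,%s) =",
          " %.5f is below the expected within-group divergence %.5f"),
          nm, a, b, bp[a, b], s), call. = FALSE)
      }
      p_anc[a, b] <- max(p_anc[a, b], 0)
    }
    sp$tip_q <- q
    sp$edges_p <- .solve_quartet(p_anc)
    if (sum(sp$edges_p) * sp$length > sp$length) {
      stop(sprintf("locus '%s': configured divergences need more substituted sites than columns",
                   nm), call. = FALSE)
    }
    locus_specs[[nm]] <- sp
  }
  structure(list(seed = as.integer(seed), group_sizes = group_sizes,
                 species = species[.SIM_ROLES], forms = forms[.SIM_ROLES],
                 locus_specs = locus_specs),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed %d; groups: %s\n", x$seed,
              paste(sprintf("%s n=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  for (nm in names(x$locus_specs)) {
    sp <- x$locus_specs[[nm]]
    cat(sprintf("  %s: %d bp, ambiguity %.4f, edges(p): %s\n", nm, sp$length,
                sp$ambiguity_rate,
                paste(sprintf("%s=%.4f", names(sp$edges_p), sp$edges_p),
                      collapse = " ")))
  }
  invisible(x)
}

#' Default simulation conditions for the Neocalanus study design
#'
#' Returns the [simulation_config()] emulating the four-marker, four-group
#' study design this package was built around: 8 *N. cristatus*, 8
#' *N. plumchrus*, 16 *N. flemingeri* small form and 5 large form (37
#' specimens); loci COI (658 bp), 12S (500 bp), ITS (900 bp) and 28S
#' (400 bp) with strongly unequal divergence scales (COI >> 12S >> ITS ~
#' 28S). Between-group targets are the published mean p-distances for each
#' group pair; within-group diversities are set inside each marker's
#' published within-group bounds (COI 0.006, 12S 0.003, ITS 0.0005, 28S 0
#' substitutions/site); ambiguity codes are injected at 0.002 per base,
#' emulating sporadic electropherogram double peaks.
#'
#' @param seed Integer RNG seed.
#' @return A `sim_config`.
#' @export
neocalanus_config <- function(seed = 1L) {
  roles <- .SIM_ROLES
  bp <- function(ls, fp, fc, cp) {
    m <- matrix(0, 4, 4, dimnames = list(roles, roles))
    m["flem_large", "flem_small"] <- m["flem_small", "flem_large"] <- ls
    m["plumchrus", "flem_large"] <- m["flem_large", "plumchrus"] <- fp
    m["plumchrus", "flem_small"] <- m["flem_small", "plumchrus"] <- fp
    m["cristatus", "flem_large"] <- m["flem_large", "cristatus"] <- fc
    m["cristatus", "flem_small"] <- m["flem_small", "cristatus"] <- fc
    m["cristatus", "plumchrus"] <- m["plumchrus", "cristatus"] <- cp
    m
  }
  simulation_config(
    seed = seed,
    group_sizes = c(cristatus = 8L, plumchrus = 8L,
                    flem_small = 16L, flem_large = 5L),
    locus_specs = list(
      COI = list(length = 658L, between_p = bp(0.03586, 0.15379, 0.16190, 0.16151),
                 intra = 0.006, ambiguity_rate = 0.002),
      `12S` = list(length = 500L, between_p = bp(0.00451, 0.06703, 0.08559, 0.07596),
                   intra = 0.003, ambiguity_rate = 0.002),
      ITS = list(length = 900L, between_p = bp(0.00058, 0.00533, 0.00430, 0.00659),
                 intra = 0.0005, ambiguity_rate = 0.002),
      `28S` = list(length = 400L, between_p = bp(0.00000, 0.00813, 0.00811, 0.01081),
                   intra = 0, ambiguity_rate = 0.002)))
}

# inject two-fold IUPAC codes (double-peak surrogates) at the given
# per-base rate; the code always contains the true base
.inject_ambiguity <- function(seq, rate) {
  if (rate <= 0) return(seq)
  hits <- which(stats::runif(length(seq)) < rate)
  for (s in hits) {
    other <- sample(setdiff(c("A", "C", "G", "T"), seq[s]), 1L)
    pair <- paste(sort(c(seq[s], other)), collapse = "")
    seq[s] <- .TWOFOLD_CODE[[pair]]
  }
  seq
}

#' Simulate a multi-locus dataset
#'
#' Generates aligned sequences for every configured locus on the fixed
#' four-group topology. Per locus: a uniform-random root sequence is
#' evolved along the five quartet edges, whose substitutions are placed on
#' disjoint sites with (stochastically rounded) expected counts — so the
#' realised divergence between group ancestors matches the configured
#' between-group expectation exactly up to rounding; each specimen is then
#' the group ancestor evolved by half its group's within diversity
#' ([evolve_jc()], exact mode, star shape within groups); finally each base
#' is independently replaced by a two-fold IUPAC ambiguity code with the
#' configured rate. Fully reproducible from the seed (the caller's RNG
#' state is left untouched).
#'
#' @param config A `sim_config` (e.g. [neocalanus_config()]).
#' @return An object of class `simulated_dataset`: `dataset` (a
#'   `barcode_dataset`), `config`, and `truth` — per locus the solved edge
#'   lengths, realised per-edge substitution counts and the realised
#'   ancestor-to-ancestor difference counts.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  roles <- rep(names(config$group_sizes), config$group_sizes)
  ids <- unlist(lapply(names(config$group_sizes), function(r) {
    sprintf("%s_%02d", r, seq_len(config$group_sizes[[r]]))
  }))
  specimens <- specimen_records(data.frame(
    specimen_id = ids,
    species = config$species[roles],
    form = config$forms[roles],
    stringsAsFactors = FALSE))

  loci <- list()
  truth <- list()
  for (nm in names(config$locus_specs)) {
    sp <- config$locus_specs[[nm]]
    L <- sp$length
    k <- stats::setNames(.stoch_round(L * sp$edges_p), names(sp$edges_p))
    if (sum(k) > L) k <- floor(L * sp$edges_p)  # pathological near-saturation
    sites <- sample.int(L, sum(k))
    split_sites <- split(sites, rep(names(k), k))
    edge_sites <- lapply(stats::setNames(names(k), names(k)),
                         function(e) split_sites[[e]] %||% integer(0))
    root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    node_x <- .mutate_sites(root, edge_sites$internal)
    anc <- list(
      cristatus  = .mutate_sites(root, edge_sites$cristatus),
      plumchrus  = .mutate_sites(root, edge_sites$plumchrus),
      flem_large = .mutate_sites(node_x, edge_sites$flem_large),
      flem_small = .mutate_sites(node_x, edge_sites$flem_small))
    seqs <- matrix("", length(ids), L, dimnames = list(ids, NULL))
    for (i in seq_along(ids)) {
      s <- evolve_jc(anc[[roles[i]]], sp$intra[[roles[i]]] / 2, "exact")
      seqs[i, ] <- .inject_ambiguity(s, sp$ambiguity_rate)
    }
    loci[[nm]] <- aligned_locus(seqs, nm)
    anc_div <- matrix(0L, 4, 4, dimnames = list(.SIM_ROLES, .SIM_ROLES))
    for (a in .SIM_ROLES) for (b in .SIM_ROLES) {
      anc_div[a, b] <- sum(anc[[a]] != anc[[b]])
    }
    truth[[nm]] <- list(edges_p = sp$edges_p, edge_counts = k,
                        ancestor_diff = anc_div, ancestors = anc)
  }
  structure(list(dataset = build_dataset(loci, specimens),
                 config = config, truth = truth),
            class = "simulated_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("<simulated_dataset>\n")
  print(x$dataset)
  invisible(x)
}

#' Simulate a fresh specimen sequence from a configured group
#'
#' Draws a new specimen from the same process as [simulate_dataset()] —
#' the group's ancestral sequence evolved by half the within-group
#' diversity — without ambiguity injection. Useful as a query for
#' [assign_specimen()] with known truth.
#'
#' @param sim A `simulated_dataset`.
#' @param locus_name Locus to draw from.
#' @param role Group role (`"cristatus"`, `"plumchrus"`, `"flem_large"`,
#'   `"flem_small"`).
#' @return Character vector sequence.
#' @export
simulate_query <- function(sim, locus_name, role) {
  stopifnot(inherits(sim, "simulated_dataset"))
  role <- match.arg(role, .SIM_ROLES)
  sp <- sim$config$locus_specs[[locus_name]]
  if (is.null(sp)) stop(sprintf("unknown locus '%s'", locus_name), call. = FALSE)
  evolve_jc(sim$truth[[locus_name]]$ancestors[[role]], sp$intra[[role]] / 2,
            "exact")
}

#' Group key used in simulated metadata for a role
#'
#' @param config A `sim_config`.
#' @param role One of the four tip roles.
#' @return The group key (`species` or `species|form`) that
#'   [simulate_dataset()] emits for the role.
#' @export
role_group <- function(config, role) {
  role <- match.arg(role, .SIM_ROLES)
  group_key(config$species[[role]], config$forms[[role]])
}
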