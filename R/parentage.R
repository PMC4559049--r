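# Likelihood-based parentage assignment with a genotyping-error model,
# unsampled-parent priors, posterior filtering, greedy consistent pedigree
# assembly and triad-based directionality.

#' Parentage-analysis configuration
#'
#' @param N_f_max,N_m_max Assumed numbers of candidate mothers/fathers in
#'   the population (sampled plus unsampled); the unsampled-parent prior
#'   mass is proportional to `N_max` minus the number sampled of that sex.
#' @param epsilon Per-allele typing error assumed by the likelihood model.
#' @param posterior_threshold Minimum posterior probability for an
#'   assignment to be retained, in (0.5, 1].
#' @return List of class `parentage_config`.
#' @export
parentage_config <- function(N_f_max = 663, N_m_max = 516,
                             epsilon = 1.538e-4,
                             posterior_threshold = 0.95) {
  if (posterior_threshold <= 0.5 || posterior_threshold > 1) {
    stop("posterior_threshold must lie in (0.5, 1]")
  }
  if (epsilon < 0 || epsilon > 0.05) stop("epsilon must lie in [0, 0.05]")
  if (N_f_max < 1 || N_m_max < 1) stop("candidate pool sizes must be >= 1")
  structure(list(N_f_max = N_f_max, N_m_max = N_m_max, epsilon = epsilon,
                 posterior_threshold = posterior_threshold),
            class = "parentage_config")
}

#' Genotype-level error model
#'
#' Composes a symmetric per-allele miscall of probability `epsilon` into a
#' 3 x 3 matrix of P(observed genotype | true genotype); each row sums to 1.
#'
#' @param epsilon Per-allele miscall probability in [0, 1].
#' @return Matrix with rows = true genotypes (AA, AB, BB), columns =
#'   observed.
#' @examples
#' genotype_error_matrix(0)      # identity
#' @export
genotype_error_matrix <- function(epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  e <- epsilon
  k <- 1 - e
  matrix(c(
    k^2,       2 * e * k,     e^2,
    e * k,     k^2 + e^2,     e * k,
    e^2,       2 * e * k,     k^2
  ), 3, 3, byrow = TRUE,
  dimnames = list(true = c("AA", "AB", "BB"),
                  obs = c("AA", "AB", "BB")))
}

# TR[to, tm, tf]: Mendelian transmission probabilities (B-count codes + 1)
.transmission_array <- function() {
  TR <- array(0, c(3, 3, 3))
  for (gm in 0:2) {
    for (gf in 0:2) {
      pm <- gm / 2
      pf <- gf / 2
      TR[, gm + 1, gf + 1] <- c((1 - pm) * (1 - pf),
                                pm * (1 - pf) + (1 - pm) * pf,
                                pm * pf)
    }
  }
  TR
}

#' Mendelian transmission probability
#'
#' Probability of an offspring genotype given both parental genotypes at a
#' biallelic autosomal locus.
#'
#' @param g_o,g_m,g_f Genotype codes (0, 1, 2 = B-allele count).
#' @return A probability; over `g_o` in 0..2 the values sum to 1.
#' @examples
#' transmission_prob(1, 0, 2)   # AB from AA x BB: certain
#' transmission_prob(0, 1, 1)   # AA from AB x AB: 0.25
#' @export
transmission_prob <- function(g_o, g_m, g_f) {
  stopifnot(all(c(g_o, g_m, g_f) %in% 0:2))
  .transmission_array()[g_o + 1, g_m + 1, g_f + 1]
}

# Per-locus likelihood lookup tables. Observed states are indexed 1..4
# (AA, AB, BB, missing-or-invalid). All likelihoods are conditional on the
# observed parental genotypes: parental true genotypes enter through their
# posterior given the observation (HWE prior for a missing observation), so
# triad, single-parent and no-parent hypotheses are directly comparable.
#  T3[L, 64]: offspring obs x mother obs x father obs (flattened)
#  T2[L, 16]: offspring obs x single-parent obs, co-parent drawn from HWE
#  L0[L, 4]:  offspring obs under HWE alone
.tables_cache <- new.env(parent = emptyenv())

.parentage_tables <- function(freq_a, epsilon) {
  if (!is.null(.tables_cache$freq_a) &&
      identical(.tables_cache$freq_a, freq_a) &&
      identical(.tables_cache$epsilon, epsilon)) {
    return(.tables_cache$tabs)
  }
  tabs <- .parentage_tables_build(freq_a, epsilon)
  .tables_cache$freq_a <- freq_a
  .tables_cache$epsilon <- epsilon
  .tables_cache$tabs <- tabs
  tabs
}

.parentage_tables_build <- function(freq_a, epsilon) {
  L <- length(freq_a)
  TR <- .transmission_array()
  E <- genotype_error_matrix(epsilon)
  T3 <- matrix(0, L, 64)
  T2 <- matrix(0, L, 16)
  L0 <- matrix(0, L, 4)
  for (l in seq_len(L)) {
    p <- freq_a[l]
    h <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
    offlik <- cbind(E, 1)                         # [true, obs-state]
    post <- matrix(0, 3, 4)
    for (s in 1:3) {
      w <- E[, s] * h
      post[, s] <- if (sum(w) > 0) w / sum(w) else h
    }
    post[, 4] <- h
    T2mend <- matrix(0, 3, 3)                     # [to, tm], father ~ HWE
    for (tm in 1:3) T2mend[, tm] <- TR[, tm, ] %*% h
    A3 <- array(0, c(4, 4, 4))
    A2 <- matrix(0, 4, 4)
    for (to in 1:3) {
      for (tm in 1:3) {
        A2 <- A2 + T2mend[to, tm] * (offlik[to, ] %o% post[tm, ])
        for (tf in 1:3) {
          w <- TR[to, tm, tf]
          if (w == 0) next
          A3 <- A3 + w * (offlik[to, ] %o% post[tm, ] %o% post[tf, ])
        }
      }
    }
    T3[l, ] <- as.vector(A3)
    T2[l, ] <- as.vector(A2)
    L0[l, ] <- as.vector(h %*% offlik)
  }
  list(T3 = T3, T2 = T2, L0 = L0)
}

# observed genotype state 1..4 (missing and invalid collapse to 4)
.obs_state <- function(g) ifelse(geno_valid(g), g + 1L, 4L)

#' Log-likelihood of a parent-pair (triad) hypothesis
#'
#' Per-locus conditional likelihood of the offspring's observed genotype
#' given both candidate parents' observed genotypes: true genotypes are
#' marginalized under the error model, parents weighted by their posterior
#' given observation (HWE prior), and offspring drawn by Mendelian
#' transmission. Loci multiply; missing calls are marginalized. With
#' `epsilon = 0` an opposite-homozygote exclusion at any locus gives
#' `-Inf`.
#'
#' @param g_o,g_m,g_f Genotype code vectors over the same autosomal loci.
#' @param freq_a Per-locus A-allele frequencies.
#' @param epsilon Assumed per-allele typing error.
#' @return Log-likelihood (natural log).
#' @export
triad_loglik <- function(g_o, g_m, g_f, freq_a, epsilon) {
  tabs <- .parentage_tables(freq_a, epsilon)
  idx <- .obs_state(g_o) + 4L * (.obs_state(g_m) - 1L) +
    16L * (.obs_state(g_f) - 1L)
  sum(log(tabs$T3[cbind(seq_along(freq_a), idx)]))
}

#' Log-likelihood of a single-parent (dyad) hypothesis
#'
#' As [triad_loglik()] with the unobserved co-parent's transmitted allele
#' drawn from the population allele frequencies.
#'
#' @inheritParams triad_loglik
#' @param g_p Genotype codes of the candidate parent.
#' @return Log-likelihood.
#' @export
dyad_loglik <- function(g_o, g_p, freq_a, epsilon) {
  tabs <- .parentage_tables(freq_a, epsilon)
  idx <- .obs_state(g_o) + 4L * (.obs_state(g_p) - 1L)
  sum(log(tabs$T2[cbind(seq_along(freq_a), idx)]))
}

# log(sum(exp(x))) without overflow
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Identify the offspring within a triad
#'
#' Given three genotypes known to form a parent-parent-offspring trio,
#' returns the index of the member whose observed genotype is most likely
#' under Mendelian transmission from the other two (the triad-likelihood
#' hypothesis set); ties go to the smallest index.
#'
#' @param g1,g2,g3 Genotype code vectors over the same loci.
#' @inheritParams triad_loglik
#' @return Integer 1, 2 or 3.
#' @export
infer_triad_offspring <- function(g1, g2, g3, freq_a, epsilon) {
  gl <- list(g1, g2, g3)
  ll <- vapply(1:3, function(i) {
    par <- setdiff(1:3, i)
    triad_loglik(gl[[i]], gl[[par[1]]], gl[[par[2]]], freq_a, epsilon)
  }, numeric(1))
  which.max(ll)
}

#' Assign parentage by posterior filtering
#'
#' For every focal individual, enumerates parent hypotheses -- (sampled
#' mother, sampled father), (sampled single parent, unsampled co-parent),
#' (both unsampled) -- scores each by conditional likelihood times a prior
#' that spreads each sex's parent slot uniformly over `N_max` candidates
#' (unsampled mass proportional to `N_max` minus the number sampled), and
#' normalizes to posteriors. The best hypothesis naming at least one
#' sampled parent becomes the focal individual's assignment; assignments
#' with posterior at or above the configured threshold are retained.
#'
#' Candidate parents for the triad enumeration are prefiltered by their
#' single-parent likelihood ratio against the unrelated hypothesis; all
#' sampled candidates contribute to the posterior normalization through the
#' dyad hypotheses regardless.
#'
#' @param inds An `individual_set` with sexes called (see [call_sexes()]).
#' @param config A [parentage_config()].
#' @param freq_a Autosomal A-allele frequencies; estimated from `inds` if
#'   omitted.
#' @param details If `TRUE`, attach the per-offspring hypothesis tables.
#' @param lr_keep,max_candidates Prefilter: candidates enter the triad
#'   enumeration when their dyad log-likelihood ratio exceeds `lr_keep`, up
#'   to `max_candidates` per sex.
#' @param forbidden Optional named list mapping a focal individual's id to
#'   ids excluded from its candidate parents (used by
#'   [reconstruct_pedigree()] to bar an individual's own pedigree
#'   descendants, whose parent-offspring likelihoods are symmetric with the
#'   true direction).
#' @return List of class `parentage_result`: `assignments` (one row per
#'   focal individual: `offspring`, `mother`, `father`, the best
#'   hypothesis's `loglik`, `lr` and `posterior`, the per-parent marginal
#'   posteriors `mother_post`/`father_post` summed over co-parent
#'   hypotheses, and `arity`), `best_triads` (each focal's best parent-pair
#'   hypothesis, used for provisional direction resolution), `retained`
#'   (parent edges whose marginal posterior clears the threshold), `config`,
#'   `freq_a`, and optionally `hypotheses`.
#' @export
assign_parentage <- function(inds, config = parentage_config(),
                             freq_a = NULL, details = FALSE,
                             lr_keep = 0, max_candidates = 15,
                             forbidden = NULL) {
  stopifnot(inherits(inds, "individual_set"),
            inherits(config, "parentage_config"))
  if (is.null(inds$info$sex)) stop("call_sexes() must be run first")
  auto <- panel_cols(inds$panel, "autosomal")
  G <- inds$genotypes[, auto, drop = FALSE]
  if (is.null(freq_a)) freq_a <- estimate_allele_freqs(G)
  ok <- !is.na(freq_a) & freq_a > 0 & freq_a < 1
  G <- G[, ok, drop = FALSE]
  freq_a <- freq_a[ok]

  ids <- inds$info$individual_id
  sex <- inds$info$sex
  n <- length(ids)
  nF <- sum(sex == "F")
  nM <- sum(sex == "M")
  if (config$N_f_max < nF) stop("N_f_max below the number of sampled females")
  if (config$N_m_max < nM) stop("N_m_max below the number of sampled males")
  Uf <- config$N_f_max - nF
  Um <- config$N_m_max - nM
  lNf <- log(config$N_f_max)
  lNm <- log(config$N_m_max)

  tabs <- .parentage_tables(freq_a, config$epsilon)
  S <- matrix(.obs_state(G), n, ncol(G))
  L <- ncol(G)

  # DY[o, p]: single-parent log-likelihood; L0: unrelated log-likelihood
  DY <- matrix(0, n, n)
  L0 <- numeric(n)
  for (l in seq_len(L)) {
    T2l <- log(matrix(tabs$T2[l, ], 4, 4))
    DY <- DY + T2l[S[, l], S[, l]]
    L0 <- L0 + log(tabs$L0[l, ])[S[, l]]
  }

  lT3 <- log(tabs$T3)
  triad_ll <- function(o, ms, fs) {
    # vector of triad logliks of offspring o against each (m, f) pair
    vapply(seq_along(ms), function(k) {
      idx <- S[o, ] + 4L * (S[ms[k], ] - 1L) + 16L * (S[fs[k], ] - 1L)
      sum(lT3[cbind(seq_len(L), idx)])
    }, numeric(1))
  }

  rows <- vector("list", n)
  best_tri <- vector("list", n)
  cache <- vector("list", n)
  hyps <- if (details) vector("list", n) else NULL
  for (o in seq_len(n)) {
    banned <- if (!is.null(forbidden)) match(forbidden[[ids[o]]], ids)
              else integer(0)
    allowed <- setdiff(seq_len(n), c(o, banned))
    fem <- allowed[sex[allowed] == "F"]
    mal <- allowed[sex[allowed] == "M"]
    pick <- function(cand) {
      lr <- DY[o, cand] - L0[o]
      keep <- cand[lr > lr_keep]
      keep[order(DY[o, keep], decreasing = TRUE)][
        seq_len(min(length(keep), max_candidates))]
    }
    km <- pick(fem)
    kf <- pick(mal)

    grid <- if (length(km) && length(kf)) {
      expand.grid(m = km, f = kf, KEEP.OUT.ATTRS = FALSE)
    } else {
      data.frame(m = integer(0), f = integer(0))
    }
    tri <- if (nrow(grid)) triad_ll(o, grid$m, grid$f) else numeric(0)

    lw <- c(
      if (nrow(grid)) -lNf - lNm + tri,
      if (length(fem) && Um > 0) -lNf + log(Um) - lNm + DY[o, fem],
      if (length(mal) && Uf > 0) log(Uf) - lNf - lNm + DY[o, mal],
      log(max(Uf, 0)) - lNf + log(max(Um, 0)) - lNm + L0[o]
    )
    mother <- c(if (nrow(grid)) ids[grid$m],
                if (length(fem) && Um > 0) ids[fem],
                if (length(mal) && Uf > 0) rep(NA_character_, length(mal)),
                NA_character_)
    father <- c(if (nrow(grid)) ids[grid$f],
                if (length(fem) && Um > 0) rep(NA_character_, length(fem)),
                if (length(mal) && Uf > 0) ids[mal],
                NA_character_)
    ll <- c(tri,
            if (length(fem) && Um > 0) DY[o, fem],
            if (length(mal) && Uf > 0) DY[o, mal],
            L0[o])

    post <- exp(lw - .logsumexp(lw))
    lr_all <- ll - L0[o]
    top <- order(lr_all, decreasing = TRUE)[
      seq_len(min(length(lr_all), 150L))]
    cache[[o]] <- data.frame(mother = mother[top], father = father[top],
                             lr = lr_all[top], stringsAsFactors = FALSE)
    if (details) {
      hyps[[o]] <- data.frame(mother = mother, father = father,
                              loglik = ll, posterior = post,
                              stringsAsFactors = FALSE)
    }
    sampled <- !is.na(mother) | !is.na(father)
    if (!any(sampled)) next
    best <- which(sampled)[which.max(post[sampled])]
    # marginal posterior of each named parent: the summed posterior of all
    # hypotheses (any co-parent, sampled or not) naming that parent
    marg <- function(parent, vec) {
      if (is.na(parent)) NA_real_ else sum(post[!is.na(vec) & vec == parent])
    }
    rows[[o]] <- data.frame(
      offspring = ids[o],
      mother = mother[best], father = father[best],
      loglik = ll[best], lr = ll[best] - L0[o],
      posterior = post[best],
      mother_post = marg(mother[best], mother),
      father_post = marg(father[best], father),
      arity = if (!is.na(mother[best]) && !is.na(father[best])) "triad"
              else "dyad",
      stringsAsFactors = FALSE
    )
    if (nrow(grid)) {
      bt <- which.max(tri)
      tri_post <- post[bt]    # triad block comes first in the weight vector
      best_tri[[o]] <- data.frame(
        offspring = ids[o],
        mother = ids[grid$m[bt]], father = ids[grid$f[bt]],
        loglik = tri[bt], lr = tri[bt] - L0[o], posterior = tri_post,
        mother_post = marg(ids[grid$m[bt]], mother),
        father_post = marg(ids[grid$f[bt]], father),
        arity = "triad", stringsAsFactors = FALSE
      )
    }
  }
  empty <- data.frame(offspring = character(0),
                      mother = character(0), father = character(0),
                      loglik = numeric(0), lr = numeric(0),
                      posterior = numeric(0), mother_post = numeric(0),
                      father_post = numeric(0), arity = character(0),
                      stringsAsFactors = FALSE)
  assignments <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(assignments)) assignments <- empty
  best_triads <- do.call(rbind,
                         best_tri[!vapply(best_tri, is.null, logical(1))])
  if (is.null(best_triads)) best_triads <- empty

  # a parent edge is retained when that parent's marginal posterior clears
  # the threshold; the co-parent may fail independently (triad -> dyad)
  thr <- config$posterior_threshold
  ret <- assignments
  ret$mother[!is.na(ret$mother_post) & ret$mother_post < thr] <-
    NA_character_
  ret$father[!is.na(ret$father_post) & ret$father_post < thr] <-
    NA_character_
  has_m <- !is.na(ret$mother)
  has_f <- !is.na(ret$father)
  ret$arity <- ifelse(has_m & has_f, "triad", "dyad")
  ret <- ret[has_m | has_f, , drop = FALSE]

  names(cache) <- ids
  out <- list(
    assignments = assignments,
    best_triads = best_triads,
    retained = ret,
    hypothesis_lrs = cache,
    config = config, freq_a = freq_a,
    sexes = stats::setNames(sex, ids)
  )
  if (details) {
    names(hyps) <- ids
    out$hypotheses <- hyps
  }
  class(out) <- "parentage_result"
  out
}

#' @export
print.parentage_result <- function(x, ...) {
  cat("<parentage_result> ", nrow(x$assignments), " candidate assignments, ",
      nrow(x$retained), " retained at posterior >= ",
      x$config$posterior_threshold, " (",
      sum(x$retained$arity == "triad"), " triads, ",
      sum(x$retained$arity == "dyad"), " dyads)\n", sep = "")
  invisible(x)
}

# is `anc` an ancestor of `id` under the mother/father maps?
.is_ancestor <- function(anc, id, mo, fa) {
  stack <- id
  seen <- character(0)
  while (length(stack)) {
    cur <- stack[[1]]
    stack <- stack[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    p <- c(mo[[cur]], fa[[cur]])
    p <- p[!is.na(p)]
    if (anc %in% p) return(TRUE)
    stack <- c(stack, p)
  }
  FALSE
}

#' Assemble retained assignments into a consistent pedigree
#'
#' Inserts parent-offspring edges greedily in decreasing order of
#' likelihood-ratio support (posterior as tiebreak), rejecting any edge
#' that would create a cycle, give an individual a second parent of the
#' same sex, or violate sex roles. Reversed configurations -- which can
#' carry high posteriors of their own -- are thereby resolved in favor of
#' the better-supported direction.
#'
#' @param par_res A `parentage_result` (its `retained` set is used), or a
#'   compatible assignments data frame.
#' @param sexes Named sex vector (required when passing a raw data frame).
#' @return Object of class `pedigree`: `parents` (id, mother, father,
#'   posterior, arity), `components` (component id, size, generation span),
#'   and the edge insertion log.
#' @export
assemble_pedigree <- function(par_res, sexes = NULL) {
  if (inherits(par_res, "parentage_result")) {
    asn <- par_res$retained
    sexes <- par_res$sexes
  } else {
    asn <- par_res
    if (is.null(sexes)) stop("sexes required when passing raw assignments")
  }
  ord <- order(-asn$lr, -asn$posterior)
  asn <- asn[ord, , drop = FALSE]

  ids <- unique(c(asn$offspring, asn$mother, asn$father))
  ids <- ids[!is.na(ids)]
  mo <- fa <- stats::setNames(rep(NA_character_, length(ids)), ids)
  meta <- list()
  edges <- list()

  try_edge <- function(parent, child, role) {
    if (is.na(parent)) return(FALSE)
    if (!is.na(sexes[[parent]]) &&
        sexes[[parent]] != (if (role == "mother") "F" else "M")) {
      return(FALSE)
    }
    slot <- if (role == "mother") mo[[child]] else fa[[child]]
    if (!is.na(slot)) return(FALSE)
    if (parent == child) return(FALSE)
    if (.is_ancestor(child, parent, mo, fa)) return(FALSE)  # would cycle
    TRUE
  }

  for (k in seq_len(nrow(asn))) {
    o <- asn$offspring[k]
    added <- character(0)
    if (try_edge(asn$mother[k], o, "mother")) {
      mo[[o]] <- asn$mother[k]
      added <- c(added, "mother")
    }
    if (try_edge(asn$father[k], o, "father")) {
      fa[[o]] <- asn$father[k]
      added <- c(added, "father")
    }
    if (length(added)) {
      meta[[o]] <- asn[k, ]
      edges[[length(edges) + 1]] <- data.frame(
        offspring = o,
        parent = c(asn$mother[k], asn$father[k])[
          c("mother", "father") %in% added],
        role = added, posterior = asn$posterior[k],
        stringsAsFactors = FALSE)
    }
  }

  linked <- !is.na(mo) | !is.na(fa)
  parents <- data.frame(
    id = ids, mother = unname(mo), father = unname(fa),
    posterior = vapply(ids, function(i)
      if (!is.null(meta[[i]])) meta[[i]]$posterior else NA_real_,
      numeric(1)),
    arity = vapply(ids, function(i) {
      nm <- sum(!is.na(c(mo[[i]], fa[[i]])))
      if (nm == 2) "triad" else if (nm == 1) "dyad" else NA_character_
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )

  # connected components over the inserted edges and their generation spans
  comp <- stats::setNames(seq_along(ids), ids)
  for (e in edges) {
    for (r in seq_len(nrow(e))) {
      a <- comp[[e$offspring[r]]]
      b <- comp[[e$parent[r]]]
      comp[comp == b] <- a
    }
  }
  in_ped <- ids[linked | ids %in% unlist(lapply(edges, `[[`, "parent"))]
  depth <- function(i) {
    p <- c(mo[[i]], fa[[i]])
    p <- p[!is.na(p)]
    if (!length(p)) 1L else 1L + max(vapply(p, depth, integer(1)))
  }
  comp_df <- do.call(rbind, lapply(unique(comp[in_ped]), function(cid) {
    members <- names(comp)[comp == cid & names(comp) %in% in_ped]
    data.frame(component = cid, size = length(members),
               span = max(vapply(members, depth, integer(1))),
               stringsAsFactors = FALSE)
  }))
  out <- list(parents = parents, components = comp_df,
              edges = if (length(edges)) do.call(rbind, edges) else NULL,
              sexes = sexes)
  class(out) <- "pedigree"
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> ", sum(!is.na(x$parents$mother) | !is.na(x$parents$father)),
      " offspring with parents; ", nrow(x$components),
      " disjoint pedigrees (sizes ",
      paste(range(x$components$size), collapse = "-"),
      ", mean ", round(mean(x$components$size), 2), ")\n", sep = "")
  invisible(x)
}

#' Reconstruct a pedigree by iterated constrained reassignment
#'
#' A parent-offspring likelihood is symmetric in direction, so a focal
#' individual's own offspring compete with its true parents for posterior
#' mass (and, for well-sampled families, can depress a true assignment
#' below the retention threshold). This wrapper approximates a joint
#' pedigree-space search: it assigns parentage, assembles a consistent
#' pedigree, and then reassigns with each individual's current pedigree
#' descendants excluded from its candidate parents, iterating until the
#' pedigree stabilizes.
#'
#' @param inds An `individual_set` with sexes called.
#' @param config A [parentage_config()].
#' @param max_iter Maximum reassignment passes.
#' @param ... Passed to [assign_parentage()].
#' @return List with `parentage` (the final `parentage_result`) and
#'   `pedigree` (assembled, with dyads oriented).
#' @export
reconstruct_pedigree <- function(inds, config = parentage_config(),
                                 max_iter = 3, ...) {
  pr <- assign_parentage(inds, config, ...)
  ped <- orient_dyads(assemble_pedigree(pr))
  prev_par <- NULL
  for (it in seq_len(max_iter)) {
    # provisional assembly over ALL assignments plus each focal's best
    # parent-pair hypothesis (not only retained rows): edges are ordered by
    # a coupled direction score, so a true assignment diluted below the
    # posterior threshold still directs the exclusions
    prov_rows <- rbind(pr$assignments, pr$best_triads)
    if (!nrow(prov_rows)) break
    prov <- assemble_pedigree(prov_rows, sexes = pr$sexes)
    forb <- .descendant_map(prov)
    if (!length(forb)) break
    pr <- assign_parentage(inds, config, forbidden = forb, ...)
    ped <- orient_dyads(assemble_pedigree(pr))
    same <- identical(ped$parents[, c("id", "mother", "father")], prev_par)
    prev_par <- ped$parents[, c("id", "mother", "father")]
    if (same) break
  }
  list(parentage = pr, pedigree = ped)
}


# named list: id -> all pedigree descendants of id
.descendant_map <- function(ped) {
  pr <- ped$parents
  kids <- list()
  for (i in seq_len(nrow(pr))) {
    for (p in c(pr$mother[i], pr$father[i])) {
      if (!is.na(p)) kids[[p]] <- c(kids[[p]], pr$id[i])
    }
  }
  if (!length(kids)) return(list())
  desc_of <- function(id) {
    out <- character(0)
    stack <- kids[[id]]
    while (length(stack)) {
      cur <- stack[[1]]
      stack <- stack[-1]
      if (cur %in% out) next
      out <- c(out, cur)
      stack <- c(stack, kids[[cur]])
    }
    out
  }
  stats::setNames(lapply(names(kids), desc_of), names(kids))
}

#' Orient parent-offspring dyads
#'
#' Triad members are oriented by construction (the offspring is the member
#' whose genotype both co-members jointly explain). A pure dyad is a
#' symmetric parent-offspring relationship: it is marked oriented only when
#' the reverse orientation is structurally impossible in the assembled
#' pedigree (the assigned parent already has a parent of the focal
#' individual's sex role, or the reverse edge would create a cycle);
#' otherwise it is retained unoriented and excluded from dispersal
#' distances.
#'
#' @param ped A `pedigree` from [assemble_pedigree()].
#' @return `ped` with `mother_oriented` and `father_oriented` logical
#'   columns added to `parents`.
#' @export
orient_dyads <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  pr <- ped$parents
  mo <- stats::setNames(pr$mother, pr$id)
  fa <- stats::setNames(pr$father, pr$id)
  sexes <- ped$sexes

  check <- function(o, p, role) {
    # TRUE if the o -> p reverse orientation is impossible (so p -> o is
    # forced); evaluated with this dyad's own edge removed
    mo2 <- mo
    fa2 <- fa
    if (role == "mother") mo2[[o]] <- NA_character_ else
      fa2[[o]] <- NA_character_
    osex <- if (o %in% names(sexes)) sexes[[o]] else NA_character_
    if (is.na(osex) || osex == "undetermined") return(FALSE)
    slot <- if (osex == "F") mo2[[p]] else fa2[[p]]
    if (!is.na(slot)) return(TRUE)
    if (.is_ancestor(p, o, mo2, fa2)) return(TRUE)
    FALSE
  }

  orient_one <- function(i, role) {
    p <- if (role == "mother") pr$mother[i] else pr$father[i]
    if (is.na(p)) return(NA)
    if (!is.na(pr$arity[i]) && pr$arity[i] == "triad") return(TRUE)
    check(pr$id[i], p, role)
  }
  pr$mother_oriented <- vapply(seq_len(nrow(pr)), orient_one,
                               logical(1), role = "mother")
  pr$father_oriented <- vapply(seq_len(nrow(pr)), orient_one,
                               logical(1), role = "father")
  ped$parents <- pr
  ped
}
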