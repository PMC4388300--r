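# Structured-coalescent simulator with migration and demographic events,
# following ms conventions: time in units of 4*N0 generations, migration
# matrix entries are 4*N0*m (the backward per-lineage migration rate per
# unit time), pairwise coalescence rate 2/x_i in a deme of relative size
# x_i, and mutations dropped at rate theta per unit total branch length.
# These rate constants are pinned by the calibration tests (panmictic
# E[TMRCA(2)] = 0.5, E[S] = theta * a1(n)) and by a distributional
# cross-check against an independent coalescent implementation.

#' Construct a demographic model
#'
#' @param samples Integer vector of haploid sample sizes per population.
#' @param theta Population-scaled mutation rate 4*N0*mu per locus.
#' @param migration Square matrix `M` with `M[i, j]` = scaled backward
#'   migration rate 4*N0*m of lineages in `i` moving to `j` (diagonal
#'   ignored); default no migration.
#' @param sizes Relative population sizes x_i (N_i / N0); default 1.
#' @param events Data frame with columns `time` (4*N0 units), `kind`
#'   (`"join"` or `"resize"`), `i`, `j` (join sink), `x` (new size);
#'   applied in time order, command order at ties.
#' @param nreps Bookkeeping: replicate count from a parsed ms command.
#' @return A `demographic_model` object.
#' @export
demographic_model <- function(samples, theta, migration = NULL, sizes = NULL,
                              events = NULL, nreps = NA_integer_) {
  k <- length(samples)
  samples <- as.integer(samples)
  if (any(samples < 0) || sum(samples) < 2) {
    fatal("need at least 2 haploid samples in total", class = "divscan_config_error")
  }
  if (is.null(migration)) migration <- matrix(0, k, k)
  migration <- as.matrix(migration)
  diag(migration) <- 0
  if (!all(dim(migration) == k) || any(migration < 0)) {
    fatal("migration must be a k x k matrix with non-negative entries",
          class = "divscan_config_error")
  }
  if (is.null(sizes)) sizes <- rep(1, k)
  if (length(sizes) != k || any(sizes <= 0)) {
    fatal("sizes must be positive, one per population", class = "divscan_config_error")
  }
  if (is.null(events)) {
    events <- tibble::tibble(time = numeric(), kind = character(),
                             i = integer(), j = integer(), x = numeric())
  } else {
    events <- tibble::as_tibble(events)
    events <- events[order(events$time), ]   # stable: command order at ties
    if (any(events$time < 0)) fatal("event times must be >= 0",
                                    class = "divscan_config_error")
  }
  model <- structure(list(n_pops = k, samples = samples, theta = theta,
                          migration = migration, sizes = sizes,
                          events = events, nreps = nreps),
                     class = "demographic_model")
  validate_model_convergence(model)
  model
}

# a history is non-convergent if more than one deme survives all joins and
# the surviving demes are not connected by migration
validate_model_convergence <- function(model) {
  k <- model$n_pops
  alive <- rep(TRUE, k)
  M <- model$migration
  ev <- model$events
  for (r in seq_len(nrow(ev))) {
    if (ev$kind[r] == "join") { alive[ev$i[r]] <- FALSE; M[, ev$i[r]] <- 0; M[ev$i[r], ] <- 0 }
  }
  if (sum(alive) > 1) {
    # surviving demes must form one connected component under migration
    adj <- (M[alive, alive, drop = FALSE] > 0) | t(M[alive, alive, drop = FALSE] > 0)
    reach <- rep(FALSE, sum(alive)); reach[1] <- TRUE
    repeat {
      nxt <- reach | apply(adj[reach, , drop = FALSE], 2, any)
      if (all(nxt == reach)) break
      reach <- nxt
    }
    if (!all(reach)) {
      fatal("model never coalesces: populations stay isolated with no final join",
            class = "divscan_config_error")
    }
  }
  invisible(model)
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("<demographic_model> %d population(s), samples (%s), theta = %g\n",
              x$n_pops, paste(x$samples, collapse = ", "), x$theta))
  if (any(x$migration > 0)) cat("  migration: yes\n") else cat("  migration: none\n")
  if (nrow(x$events) > 0) {
    cat(sprintf("  events: %s\n", paste(
      ifelse(x$events$kind == "join",
             sprintf("join(%d->%d)@%g", x$events$i, x$events$j, x$events$time),
             sprintf("resize(%d,%g)@%g", x$events$i, x$events$x, x$events$time)),
      collapse = ", ")))
  }
  invisible(x)
}

#' Parse an ms-style command line into a demographic model
#'
#' Understands the flags `-t`, `-I` (with optional trailing island-model
#' rate), `-ma` (full matrix with `x` diagonal placeholders, also accepted
#' as the fused token `-max`), `-n`, `-ej`, `-en`. Unicode minus and
#' multiplication signs, as found in typeset text, are normalised first.
#'
#' @param text The command line, e.g.
#'   `"ms 60 10000 -t 34.6 -I 3 20 20 20 -ej 0.761 3 2 ..."`.
#' @return A `demographic_model`.
#' @export
parse_ms_command <- function(text) {
  text <- gsub("−", "-", text)   # unicode minus
  text <- gsub("×", "x", text)   # multiplication sign used as placeholder
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(toks) > 0 && toks[1] == "ms") toks <- toks[-1]
  if (length(toks) < 2) fatal("ms command needs sample size and replicate count",
                              class = "divscan_config_error")
  nsam <- as.integer(toks[1]); nreps <- as.integer(toks[2])
  toks <- toks[-(1:2)]
  # fused "-max" is "-ma" followed by a diagonal placeholder
  out <- character(0)
  for (tk in toks) {
    if (tk == "-max") out <- c(out, "-ma", "x") else out <- c(out, tk)
  }
  toks <- out

  theta <- NA_real_; k <- 1L; samples <- nsam
  M <- NULL; sizes <- NULL
  events <- list()
  i <- 1L
  num <- function(tk) suppressWarnings(as.numeric(tk))
  is_num <- function(tk) !is.na(num(tk))
  while (i <= length(toks)) {
    flag <- toks[i]
    if (flag == "-t") { theta <- num(toks[i + 1]); i <- i + 2
    } else if (flag == "-I") {
      k <- as.integer(toks[i + 1])
      samples <- as.integer(toks[i + 1 + seq_len(k)])
      i <- i + 2 + k
      M <- matrix(0, k, k)
      if (i <= length(toks) && is_num(toks[i])) {   # island-model rate
        m <- num(toks[i]) / (k - 1)
        M[] <- m; diag(M) <- 0
        i <- i + 1
      }
      if (is.null(sizes)) sizes <- rep(1, k)
    } else if (flag == "-ma") {
      if (is.null(M)) fatal("-ma before -I", class = "divscan_config_error")
      entries <- toks[i + seq_len(k * k)]
      vals <- suppressWarnings(as.numeric(entries))
      M <- matrix(ifelse(is.na(vals), 0, vals), k, k, byrow = TRUE)
      diag(M) <- 0
      i <- i + 1 + k * k
    } else if (flag == "-n") {
      if (is.null(sizes)) sizes <- rep(1, k)
      sizes[as.integer(toks[i + 1])] <- num(toks[i + 2])
      i <- i + 3
    } else if (flag == "-ej") {
      ev_t <- num(toks[i + 1]); ev_i <- as.integer(toks[i + 2])
      ev_j <- as.integer(toks[i + 3])
      events[[length(events) + 1]] <-
        tibble::tibble(time = ev_t, kind = "join", i = ev_i, j = ev_j,
                       x = NA_real_)
      i <- i + 4
    } else if (flag == "-en") {
      ev_t <- num(toks[i + 1]); ev_i <- as.integer(toks[i + 2])
      ev_x <- num(toks[i + 3])
      events[[length(events) + 1]] <-
        tibble::tibble(time = ev_t, kind = "resize", i = ev_i,
                       j = NA_integer_, x = ev_x)
      i <- i + 4
    } else {
      fatal(paste0("unknown ms flag: ", flag), class = "divscan_config_error")
    }
  }
  if (is.na(theta)) fatal("ms command lacks -t theta", class = "divscan_config_error")
  if (sum(samples) != nsam) {
    fatal(sprintf("-I sample sizes sum to %d but nsam is %d", sum(samples), nsam),
          class = "divscan_config_error")
  }
  ev <- if (length(events) > 0) dplyr::bind_rows(events) else NULL
  demographic_model(samples, theta, migration = M, sizes = sizes,
                    events = ev, nreps = nreps)
}

#' Canonical ms command string for a model
#'
#' `parse_ms_command(format_ms_command(m))` reproduces `m`; formatting a
#' parsed command is idempotent.
#'
#' @param model A `demographic_model`.
#' @return A single character string.
#' @export
format_ms_command <- function(model) {
  fmt <- function(v) sub("\\.?0+$", "", sprintf("%.10f", v))
  parts <- c("ms", sum(model$samples),
             if (is.na(model$nreps)) 1L else model$nreps,
             "-t", fmt(model$theta))
  if (model$n_pops > 1) {
    parts <- c(parts, "-I", model$n_pops, model$samples)
    if (any(model$migration > 0)) {
      ent <- t(model$migration)       # row-major output
      ent <- as.vector(ent)
      ent <- fmt(ent)
      ent[as.vector(t(diag(model$n_pops) == 1))] <- "x"
      parts <- c(parts, "-ma", ent)
    }
    for (p in which(model$sizes != 1)) parts <- c(parts, "-n", p, fmt(model$sizes[p]))
  }
  ev <- model$events
  for (r in seq_len(nrow(ev))) {
    if (ev$kind[r] == "join") {
      parts <- c(parts, "-ej", fmt(ev$time[r]), ev$i[r], ev$j[r])
    } else {
      parts <- c(parts, "-en", fmt(ev$time[r]), ev$i[r], fmt(ev$x[r]))
    }
  }
  paste(parts, collapse = " ")
}

#' Bundled isolation-with-migration demography of the Heliconius community
#'
#' The three-population isolation-with-migration parameterization for
#' *H. cydno*, *H. pachinus* and *H. melpomene* (20 haploid genomes each,
#' theta = 34.6 per 5 kbp locus, asymmetric migration, staged population
#' joins at 0.761 and 2.48 coalescent time units with associated size
#' changes), as inferred from genome-wide polymorphism data. Returned both
#' with the migration matrix and with migration removed, the contrast used
#' to quantify how much interspecific gene flow suppresses neutral
#' divergence.
#'
#' @return A list with elements `migration` and `no_migration`, each a
#'   `demographic_model`.
#' @export
#' @examples
#' heliconius_im_models()$migration
heliconius_im_models <- function() {
  mig <- paste("ms 60 10000 -t 34.6 -I 3 20 20 20",
               "-ma x 11.53 11.53 0 x 12.56 0 4.89 x",
               "-n 1 0.35 -n 2 1.59 -n 3 0.22",
               "-ej 0.761 3 2 -en 0.761 2 0.035 -ej 2.48 2 1 -en 2.48 1 1")
  nomig <- paste("ms 60 10000 -t 34.6 -I 3 20 20 20",
                 "-n 1 0.35 -n 2 1.59 -n 3 0.22",
                 "-ej 0.761 3 2 -en 0.761 2 0.035 -ej 2.48 2 1 -en 2.48 1 1")
  list(migration = parse_ms_command(mig),
       no_migration = parse_ms_command(nomig))
}

#' Simulate one genealogy under the structured coalescent
#'
#' Competing exponentials: within-deme pairwise coalescence at rate 2/x_i
#' and per-lineage migration at rate `M[i, j]`, with demographic events
#' applied at their scheduled times (a join moves all lineages of deme i
#' into deme j and shuts migration into i). Uses the current RNG state.
#'
#' @param model A `demographic_model`.
#' @return A `genealogy`: list with `parent` (0 for the root), `time`
#'   (node times, 4*N0 units), `n_leaves`, `leaf_pop`, `tmrca`,
#'   `total_length`.
#' @export
simulate_genealogy <- function(model) {
  k <- model$n_pops
  deme <- rep(seq_len(k), model$samples)
  n <- length(deme)
  node <- seq_len(n)
  parent <- integer(2L * n - 1L)
  time <- numeric(2L * n - 1L)
  nxt <- n + 1L
  M <- model$migration
  x <- model$sizes
  ev <- model$events
  n_ev <- nrow(ev)
  ev_i <- 1L
  t <- 0
  while (length(node) > 1L) {
    cnt <- tabulate(deme, k)
    coal <- cnt * (cnt - 1) / x
    mig <- cnt * M
    total <- sum(coal) + sum(mig)
    t_ev <- if (ev_i <= n_ev) ev$time[ev_i] else Inf
    if (total <= 0) {
      if (!is.finite(t_ev)) {
        fatal("lineages isolated forever: model validation missed a dead end",
              class = "divscan_config_error")
      }
      t <- t_ev
    } else {
      t_prop <- t + stats::rexp(1, total)
      t <- min(t_prop, t_ev)
    }
    if (t == t_ev && ev_i <= n_ev) {
      if (ev$kind[ev_i] == "join") {
        deme[deme == ev$i[ev_i]] <- ev$j[ev_i]
        M[, ev$i[ev_i]] <- 0
      } else {
        x[ev$i[ev_i]] <- ev$x[ev_i]
      }
      ev_i <- ev_i + 1L
      next
    }
    u <- stats::runif(1, 0, total)
    cs <- cumsum(c(coal, as.vector(mig)))
    pick <- findInterval(u, cs) + 1L
    if (pick <= k) {
      pair <- sample_of(which(deme == pick), 2L)
      parent[node[pair]] <- nxt
      time[nxt] <- t
      node <- c(node[-pair], nxt)
      deme <- c(deme[-pair], pick)
      nxt <- nxt + 1L
    } else {
      pick <- pick - k
      from <- (pick - 1L) %% k + 1L
      to <- (pick - 1L) %/% k + 1L
      li <- sample_of(which(deme == from), 1L)
      deme[li] <- to
    }
  }
  bl <- branch_lengths(parent, time)
  structure(list(parent = parent, time = time, n_leaves = n,
                 leaf_pop = rep(seq_len(k), model$samples),
                 tmrca = time[length(time)], total_length = sum(bl)),
            class = "genealogy")
}

# branch length above each non-root node (root entry 0)
branch_lengths <- function(parent, time) {
  bl <- numeric(length(parent))
  nz <- parent > 0
  bl[nz] <- time[parent[nz]] - time[which(nz)]
  bl
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("<genealogy> %d leaves, TMRCA = %.4g, total branch length = %.4g (4N0 units)\n",
              x$n_leaves, x$tmrca, x$total_length))
  invisible(x)
}

# leaf descendant sets for every node, as a list of integer vectors
descendant_leaves <- function(parent, n_leaves) {
  n_nodes <- length(parent)
  desc <- vector("list", n_nodes)
  for (v in seq_len(n_leaves)) desc[[v]] <- v
  # internal nodes are numbered in coalescence-time order, so children
  # always precede parents
  for (v in seq_len(n_nodes)) {
    p <- parent[v]
    if (p > 0) desc[[p]] <- c(desc[[p]], desc[[v]])
  }
  desc
}

#' Drop mutations on a genealogy to make a simulated locus
#'
#' `infinite_sites`: a Poisson(theta * total branch length) number of
#' mutations placed on branches with probability proportional to branch
#' length, each at a distinct position uniform on `[1, length]`.
#' `jukes_cantor`: mutation events at the same rate, but positions drawn
#' with replacement and each event replacing the current base by one of
#' the other three uniformly; sites with more than two alleles among the
#' leaves are dropped and counted, as are sites returned to monomorphism
#' by recurrent hits.
#'
#' @param genealogy A `genealogy`.
#' @param theta Locus-scaled mutation rate (4*N0*mu per locus).
#' @param length Locus length in bp (default 5000).
#' @param mode `"infinite_sites"` (default) or `"jukes_cantor"`.
#' @return A `sim_locus`: list with `position` (sorted), `geno` (0/1
#'   derived-allele matrix, sites x leaves), `length`, `mode`,
#'   `n_dropped_multiallelic`, `n_dropped_monomorphic`.
#' @export
drop_mutations <- function(genealogy, theta, length = 5000,
                           mode = c("infinite_sites", "jukes_cantor")) {
  mode <- match.arg(mode)
  g <- genealogy
  bl <- branch_lengths(g$parent, g$time)
  L <- sum(bl)
  empty <- function(extra_multi = 0L, extra_mono = 0L) {
    structure(list(position = integer(),
                   geno = matrix(0L, nrow = 0, ncol = g$n_leaves),
                   length = length, mode = mode,
                   n_dropped_multiallelic = extra_multi,
                   n_dropped_monomorphic = extra_mono),
              class = "sim_locus")
  }
  if (L <= 0 || theta <= 0) return(empty())
  n_mut <- stats::rpois(1, theta * L)
  if (n_mut == 0) return(empty())
  desc <- descendant_leaves(g$parent, g$n_leaves)
  branch_nodes <- which(g$parent > 0)
  if (mode == "infinite_sites") {
    n_mut <- min(n_mut, length)   # distinct positions exist for each mutation
    on <- sample(branch_nodes, n_mut, replace = TRUE, prob = bl[branch_nodes])
    pos <- sample.int(length, n_mut, replace = FALSE)
    geno <- matrix(0L, nrow = n_mut, ncol = g$n_leaves)
    for (s in seq_len(n_mut)) geno[s, desc[[on[s]]]] <- 1L
    ord <- order(pos)
    structure(list(position = pos[ord], geno = geno[ord, , drop = FALSE],
                   length = length, mode = mode,
                   n_dropped_multiallelic = 0L, n_dropped_monomorphic = 0L),
              class = "sim_locus")
  } else {
    on <- sample(branch_nodes, n_mut, replace = TRUE, prob = bl[branch_nodes])
    pos <- sample.int(length, n_mut, replace = TRUE)
    # time of each event, measured downward from the root so that events
    # on one branch can be ordered oldest-first
    ev_time <- g$time[on] + stats::runif(n_mut) * bl[on]
    n_nodes <- length(g$parent)
    keep_pos <- integer(0); keep_rows <- list()
    n_multi <- 0L; n_mono <- 0L
    for (p in unique(pos)) {
      idx <- which(pos == p)
      # propagate base states (0 = ancestral, 1..3 other bases) down the
      # tree, applying this site's events oldest-first along each branch
      st <- rep(NA_integer_, n_nodes)
      st[n_nodes] <- 0L
      for (v in rev(seq_len(n_nodes - 1L))) {
        s0 <- st[g$parent[v]]
        here <- idx[on[idx] == v]
        if (length(here) > 0) {
          for (e in here[order(ev_time[here], decreasing = TRUE)]) {
            s0 <- sample_of(setdiff(0:3, s0), 1L)
          }
        }
        st[v] <- s0
      }
      leaf_states <- st[seq_len(g$n_leaves)]
      alleles <- unique(leaf_states)
      if (length(alleles) == 1L) { n_mono <- n_mono + 1L; next }
      if (length(alleles) > 2L) { n_multi <- n_multi + 1L; next }
      # derived allele = minor...: define derived as the allele not carried
      # at the root if present, else the second observed
      anc <- st[n_nodes]
      der <- setdiff(alleles, anc)
      if (length(der) == 0) der <- alleles[2]
      keep_pos <- c(keep_pos, p)
      keep_rows[[length(keep_rows) + 1]] <- as.integer(leaf_states == der[1])
    }
    if (length(keep_pos) == 0) return(empty(n_multi, n_mono))
    geno <- do.call(rbind, keep_rows)
    ord <- order(keep_pos)
    structure(list(position = keep_pos[ord], geno = geno[ord, , drop = FALSE],
                   length = length, mode = mode,
                   n_dropped_multiallelic = n_multi, n_dropped_monomorphic = n_mono),
              class = "sim_locus")
  }
}
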