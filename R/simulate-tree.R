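# Forward simulation of the trait-dependent birth-death process: each
# lineage speciates at rate lambda(x(t)) and goes extinct at rate mu while
# its trait x performs Brownian motion (rate sigma2) with optional drift
# phi. Time is discretized on a small step; per step each lineage first
# updates its trait, then speciates or dies with probabilities lambda(x)*dt
# and mu*dt.

#' Simulate a tree under trait-dependent speciation
#'
#' @param model A [speciation_model()].
#' @param x0 Root trait value; `lambda(x0)` must be positive.
#' @param max_time Stop after this much time (Myr), or
#' @param max_tips stop at the first step where the number of extant
#'   lineages reaches exactly this count. Exactly one of the two must be
#'   given.
#' @param dt Simulation time step (Myr). Event probabilities per step are
#'   `lambda(x) dt` and `mu dt`; keep `dt` small relative to `1/lambda`.
#' @param seed Optional integer seed.
#' @param prune_extinct Drop extinct side branches (default `TRUE`).
#' @return A `phylo_dataset` (tree plus tip traits) with extra fields
#'   `extinct` (`TRUE` if the whole clade died or fewer than two tips
#'   remain, in which case `tree`/`traits` are `NULL`) and `t_stop` (the
#'   simulated time span).
#' @export
#' @examples
#' m <- speciation_model("constant", lambda0 = 0.3, mu = 0, sigma2 = 0.05)
#' sim <- simulate_tree(m, x0 = 2, max_tips = 10, seed = 1)
#' sim$tree$Nnode
simulate_tree <- function(model, x0, max_time = NULL, max_tips = NULL,
                          dt = 0.02, seed = NULL, prune_extinct = TRUE) {
  stopifnot(inherits(model, "speciation_model"))
  if (is.null(max_time) == is.null(max_tips)) {
    abort("Supply exactly one of `max_time` or `max_tips`.")
  }
  if (lambda_at(model, x0) <= 0) abort("lambda(x0) must be positive.")
  if (!is.null(max_tips) && max_tips < 2) abort("`max_tips` must be at least 2.")
  if (!is.null(max_time) && max_time <= 0) abort("`max_time` must be positive.")
  if (!is.null(seed)) set.seed(seed)
  mu <- model$pars$mu
  sigma <- sqrt(model$pars$sigma2)
  phi <- drift_of(model)

  nmax <- 1024L
  parent <- integer(nmax); t_birth <- t_end <- x_end <- numeric(nmax)
  status <- character(nmax)  # "alive", "extinct", "split"
  parent[1] <- 0L; t_birth[1] <- 0; status[1] <- "alive"
  x_cur <- c(x0); alive <- 1L; n_lin <- 1L
  t <- 0

  repeat {
    step <- if (!is.null(max_time)) min(dt, max_time - t) else dt
    if (step <= 0) break
    t_next <- t + step
    # trait diffusion
    x_cur <- x_cur + phi * step + sigma * sqrt(step) * rnorm(length(alive))
    lam <- lambda_at(model, x_cur)
    if (any((lam + mu) * step > 0.5)) {
      abort("Time step too coarse for the rates; decrease `dt`.")
    }
    u <- runif(length(alive))
    sp_ev <- which(u < lam * step)
    ex_ev <- which(u >= lam * step & u < (lam + mu) * step)
    if (!is.null(max_tips)) {
      room <- max_tips - (length(alive) - length(ex_ev))
      if (length(sp_ev) > room) sp_ev <- sort(sample(sp_ev, max(room, 0)))
    }
    # extinctions
    if (length(ex_ev) > 0) {
      ids <- alive[ex_ev]
      t_end[ids] <- t_next; x_end[ids] <- x_cur[ex_ev]; status[ids] <- "extinct"
    }
    # speciations: parent lineage ends, two daughters inherit its trait
    new_ids <- integer(0); new_x <- numeric(0)
    if (length(sp_ev) > 0) {
      ids <- alive[sp_ev]
      t_end[ids] <- t_next; x_end[ids] <- x_cur[sp_ev]; status[ids] <- "split"
      n_new <- 2L * length(ids)
      while (n_lin + n_new > nmax) {
        nmax <- nmax * 2L
        length(parent) <- nmax; length(t_birth) <- nmax
        length(t_end) <- nmax; length(x_end) <- nmax; length(status) <- nmax
      }
      new_ids <- n_lin + seq_len(n_new)
      parent[new_ids] <- rep(ids, each = 2L)
      t_birth[new_ids] <- t_next; status[new_ids] <- "alive"
      new_x <- rep(x_cur[sp_ev], each = 2L)
      n_lin <- n_lin + n_new
    }
    keep <- setdiff(seq_along(alive), c(sp_ev, ex_ev))
    alive <- c(alive[keep], new_ids)
    x_cur <- c(x_cur[keep], new_x)
    t <- t_next
    if (length(alive) == 0) break
    if (!is.null(max_tips) && length(alive) >= max_tips) break
    if (!is.null(max_time) && t >= max_time) break
  }

  if (length(alive) > 0) {
    t_end[alive] <- t; x_end[alive] <- x_cur; status[alive] <- "tip"
  }
  idx <- seq_len(n_lin)
  rec <- list(parent = parent[idx], t_birth = t_birth[idx], t_end = t_end[idx],
              x_end = x_end[idx], status = status[idx])
  extant <- which(rec$status == "tip")
  if (length(extant) < 2 && prune_extinct) {
    return(structure(list(tree = NULL, traits = NULL, extinct = TRUE, t_stop = t),
                     class = "phylo_dataset"))
  }
  keep_status <- if (prune_extinct) "tip" else c("tip", "extinct")
  res <- lineages_to_phylo(rec, keep_status)
  if (is.null(res)) {
    return(structure(list(tree = NULL, traits = NULL, extinct = TRUE, t_stop = t),
                     class = "phylo_dataset"))
  }
  out <- phylo_dataset(res$tree, res$traits)
  out$extinct <- FALSE
  out$t_stop <- t
  out
}

# Convert lineage records to an ape::phylo. Each lineage is one edge from
# its birth to its end; split lineages end in internal nodes. Unbranched
# chains left by pruning are concatenated. Returns NULL when fewer than two
# tips survive.
lineages_to_phylo <- function(rec, keep_status) {
  n <- length(rec$parent)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- rec$parent[i]
    if (p > 0L) children[[p]] <- c(children[[p]], i)
  }
  # mark lineages with any surviving descendant
  surv <- rec$status %in% keep_status
  ord <- order(rec$t_birth, decreasing = TRUE)  # children before parents
  for (i in ord) {
    p <- rec$parent[i]
    if (p > 0L && surv[i]) surv[p] <- TRUE
  }
  if (!surv[1]) return(NULL)

  # effective children after pruning, collapsing single-child chains
  eff_children <- function(i) {
    kids <- children[[i]]
    kids <- kids[surv[kids]]
    out <- list()
    for (k in kids) {
      len <- rec$t_end[k] - rec$t_birth[k]
      kk <- k
      repeat {
        gkids <- children[[kk]]
        gkids <- if (is.null(gkids)) integer(0) else gkids[surv[gkids]]
        if (rec$status[kk] %in% keep_status || length(gkids) != 1L) break
        kk <- gkids
        len <- len + rec$t_end[kk] - rec$t_birth[kk]
      }
      out[[length(out) + 1L]] <- list(id = kk, len = len)
    }
    out
  }

  # find the crown: walk down from the root lineage through single-child chains
  root_id <- 1L
  repeat {
    kids <- eff_children(root_id)
    if (rec$status[root_id] %in% keep_status && length(kids) == 0) return(NULL)
    if (length(kids) >= 2L) break
    if (length(kids) == 0L) return(NULL)
    root_id <- kids[[1]]$id
  }

  tip_ids <- integer(0); tip_x <- numeric(0)
  edges <- list(); edge_len <- numeric(0)
  node_counter <- new.env()
  assign("next_internal", 0L, envir = node_counter)

  # two passes: count tips first to number internal nodes after tips
  count_tips <- function(i) {
    kids <- eff_children(i)
    if (length(kids) == 0) 1L else sum(vapply(kids, function(k) count_tips(k$id), integer(1)))
  }
  ntip <- count_tips(root_id)
  next_tip <- 0L; next_int <- ntip

  build <- function(i) {
    kids <- eff_children(i)
    if (length(kids) == 0) {
      next_tip <<- next_tip + 1L
      tip_ids[next_tip] <<- i
      tip_x[next_tip] <<- rec$x_end[i]
      return(next_tip)
    }
    next_int <<- next_int + 1L
    me <- next_int
    for (k in kids) {
      ch <- build(k$id)
      edges[[length(edges) + 1L]] <<- c(me, ch)
      edge_len[length(edges)] <<- k$len
    }
    me
  }
  root_node <- build(root_id)

  tree <- structure(list(
    edge = do.call(rbind, edges),
    edge.length = edge_len,
    tip.label = paste0("sp", seq_len(ntip)),
    Nnode = next_int - ntip
  ), class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  traits <- setNames(tip_x, tree$tip.label)
  list(tree = tree, traits = traits)
}
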