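# Independent brute-force oracles. These deliberately share no code with the
# package: textbook array Dijkstra, recursive flood fill, exhaustive
# double-loop kernel sums and exhaustive simple-path enumeration.

# single-source Dijkstra over the 8-connected grid with mean-of-endpoints
# step costs; returns the distance to every cell (O(V^2) array scan)
ref_dijkstra_all <- function(cost, src_row, src_col, cell_size = 1) {
  nr <- nrow(cost); nc <- ncol(cost)
  dist <- matrix(Inf, nr, nc)
  done <- matrix(FALSE, nr, nc)
  dist[src_row, src_col] <- 0
  moves <- expand.grid(dr = -1:1, dc = -1:1)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  for (iter in seq_len(nr * nc)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    ur <- ((u - 1) %% nr) + 1; uc <- ((u - 1) %/% nr) + 1
    done[u] <- TRUE
    for (m in seq_len(nrow(moves))) {
      vr <- ur + moves$dr[m]; vc <- uc + moves$dc[m]
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      step <- (cost[ur, uc] + cost[vr, vc]) / 2 * cell_size *
        sqrt(moves$dr[m]^2 + moves$dc[m]^2)
      if (dist[ur, uc] + step < dist[vr, vc]) {
        dist[vr, vc] <- dist[ur, uc] + step
      }
    }
  }
  dist
}

ref_dijkstra <- function(cost, src, dst, cell_size = 1) {
  ref_dijkstra_all(cost, src[1], src[2], cell_size)[dst[1], dst[2]]
}

# queen-connected component labelling by explicit stack-based flood fill
ref_flood_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (labels[u] != 0L) next
      labels[u] <- nxt
      ur <- ((u - 1) %% nr) + 1; uc <- ((u - 1) %/% nr) + 1
      for (dr in -1:1) for (dc in -1:1) {
        vr <- ur + dr; vc <- uc + dc
        if ((dr | dc) && vr >= 1 && vr <= nr && vc >= 1 && vc <= nc) {
          v <- (vc - 1) * nr + vr
          if (mask[v] && labels[v] == 0L) stack <- c(stack, v)
        }
      }
    }
  }
  labels
}

# exhaustive pairwise Euclidean kernel sum of deleterious memberships
ref_nneg <- function(membership, del_idx, decay_alpha, maxD, cell_size = 1) {
  nr <- dim(membership)[1]; nc <- dim(membership)[2]
  out <- matrix(0, nr, nc)
  for (cr in 1:nr) for (cc in 1:nc) {
    acc <- 0
    for (kr in 1:nr) for (kc in 1:nc) {
      if (kr == cr && kc == cc) next
      d <- cell_size * sqrt((kr - cr)^2 + (kc - cc)^2)
      if (d > maxD + 1e-9) next
      p <- exp(-decay_alpha * d)
      for (i in del_idx) acc <- acc + p * membership[kr, kc, i]
    }
    out[cr, cc] <- acc
  }
  out
}

# exhaustive functional cost: weighted cost + pairwise deleterious
# resistance contributions
ref_functional_cost <- function(membership, R, del_idx, decay_alpha, maxD,
                                cell_size = 1) {
  nr <- dim(membership)[1]; nc <- dim(membership)[2]
  k <- dim(membership)[3]
  out <- matrix(0, nr, nc)
  for (cr in 1:nr) for (cc in 1:nc) {
    base <- sum(membership[cr, cc, ] * R)
    acc <- 0
    for (kr in 1:nr) for (kc in 1:nc) {
      if (kr == cr && kc == cc) next
      d <- cell_size * sqrt((kr - cr)^2 + (kc - cc)^2)
      if (d > maxD + 1e-9) next
      p <- exp(-decay_alpha * d)
      for (i in del_idx) acc <- acc + p * membership[kr, kc, i] * R[i]
    }
    out[cr, cc] <- base + acc
  }
  out
}

# exhaustive foraging complementarity: per habitat cell, Dijkstra cost
# distances to every cell, kernel-weighted forage mean over the reachable set
ref_npos <- function(forage, habitat, cost, decay_alpha, maxD,
                     cell_size = 1, alpha_cut = 0.5) {
  nr <- nrow(forage); nc <- ncol(forage)
  out <- matrix(0, nr, nc)
  for (cr in 1:nr) for (cc in 1:nc) {
    if (habitat[cr, cc] < alpha_cut) next
    d <- ref_dijkstra_all(cost, cr, cc, cell_size)
    sel <- d <= maxD + 1e-9
    sel[cr, cc] <- FALSE
    n_nb <- sum(sel)
    if (n_nb == 0) next
    out[cr, cc] <- sum(exp(-decay_alpha * d[sel]) * forage[sel]) / n_nb
  }
  out
}

# maximum product of edge probabilities over all simple paths, by recursion
ref_max_product <- function(p) {
  n <- nrow(p)
  best <- function(u, target, visited, prob) {
    if (u == target) return(prob)
    out <- 0
    for (v in seq_len(n)) {
      if (!visited[v] && p[u, v] > 0) {
        visited[v] <- TRUE
        out <- max(out, best(v, target, visited, prob * p[u, v]))
        visited[v] <- FALSE
      }
    }
    out
  }
  pstar <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    visited <- logical(n); visited[i] <- TRUE
    pstar[i, j] <- pstar[j, i] <- best(i, j, visited, 1)
  }
  pstar
}
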