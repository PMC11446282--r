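# Shared fixture builders. Everything is generated in code at test time.

# Minimal hand-placed two-residue complex: one receptor probe, one binder
# residue, with an exact CB-CB separation.
toy_pair <- function(sep = 3.5) {
  # CB atoms face each other at exactly `sep`; all other atoms point away
  binder <- tibble::tibble(
    chain = "B", resid = 1L, resname = "ALA",
    atom = c("CB", "CA", "N", "C"),
    x = c(0, 0, -1.4, 1.2), y = c(0, -1.5, -2.1, -2.3), z = 0
  )
  receptor <- tibble::tibble(
    chain = "A", resid = 178L, resname = "TYR",
    atom = c("CB", "CA", "N", "C"),
    x = c(0, 0, -1.4, 1.2), y = sep + c(0, 1.5, 2.1, 2.3), z = 0
  )
  new_structure(dplyr::bind_rows(receptor, binder), receptor_chain = "A")
}

# CDCA4-like register fixture: anchor 56, contacts 0/2/4/5 as in the
# canonical binding helix (patch1 at i and i+4, patch3 at i+2, patch2 at
# i+5).
cdca4_spec <- function(seed = 1L, ...) {
  helix_complex_spec(binder_length = 14, anchor_resid = 56,
                     binder_start = 52,
                     contacts = c("0" = "patch1", "2" = "patch3",
                                  "4" = "patch1", "5" = "patch2"),
                     seed = seed, ...)
}

# A complex plus block confidence whose metrics are fully prescribed.
scored_fixture <- function(seed = 1L, plddt = 90, interface_value = 5,
                           background_value = 25, n_binder_iface = 8) {
  extra <- c("3" = "patch1", "6" = "patch1", "7" = "flank")
  stopifnot(n_binder_iface <= 8)
  reg <- c("0" = "patch1", "1" = "patch2", "2" = "patch3",
           "4" = "patch1", "5" = "patch2")
  n_extra <- max(0, n_binder_iface - length(reg))
  spec <- helix_complex_spec(
    binder_length = 16, anchor_resid = 56, binder_start = 52,
    contacts = reg[seq_len(min(n_binder_iface, length(reg)))],
    extra_contacts = extra[seq_len(n_extra)], seed = seed)
  fx <- make_helix_complex(spec)
  conf <- make_confidence(
    fx$model, binder_iface = unique(fx$truth$binder_resid),
    receptor_iface = unique(fx$truth$receptor_resid), plddt = plddt,
    interface_value = interface_value,
    background_value = background_value)
  iface <- interface_residues(fx$model, conf = conf, site = b55_site())
  list(fx = fx, conf = conf, iface = iface)
}

# Independent RMSD oracle: minimise over rotations directly (Euler-angle
# grid + Nelder-Mead refinement), never touching the SVD-based route.
brute_force_rmsd <- function(ref, mob) {
  ref_c <- sweep(ref, 2, colMeans(ref))
  mob_c <- sweep(mob, 2, colMeans(mob))
  rot <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  obj <- function(a) {
    sqrt(mean(rowSums((mob_c %*% t(rot(a)) - ref_c)^2)))
  }
  grid <- seq(-pi, pi, length.out = 13)
  best <- NULL; best_val <- Inf
  for (a1 in grid) for (a2 in grid[grid >= -pi / 2 & grid <= pi / 2])
    for (a3 in grid) {
      v <- obj(c(a1, a2, a3))
      if (v < best_val) { best_val <- v; best <- c(a1, a2, a3) }
    }
  res <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  res$value
}

# Chain with per-residue (phi, psi): helix-loop-helix etc. Backbone only.
build_chain <- function(phis, psis, chain = "B", start_resid = 1L) {
  g <- helixscreen:::.helix_geo
  n <- length(phis)
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N
  N[1, ] <- c(0, 0, 0); CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in 2:n) {
    N[i, ] <- helixscreen:::nerf_place(N[i-1,], CA[i-1,], C[i-1,],
                                       g$b_c_n, g$a_ca_c_n, psis[i - 1])
    CA[i, ] <- helixscreen:::nerf_place(CA[i-1,], C[i-1,], N[i,],
                                        g$b_n_ca, g$a_c_n_ca, g$omega)
    C[i, ] <- helixscreen:::nerf_place(C[i-1,], N[i,], CA[i,],
                                       g$b_ca_c, g$a_n_ca_c, phis[i])
  }
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::tibble(chain = chain, resid = start_resid + i - 1L,
                   resname = "ALA", atom = c("N", "CA", "C"),
                   x = c(N[i, 1], CA[i, 1], C[i, 1]),
                   y = c(N[i, 2], CA[i, 2], C[i, 2]),
                   z = c(N[i, 3], CA[i, 3], C[i, 3]))
  }))
}

# Two 10-residue helices joined by a 5-residue extended loop (residues
# 1-10 and 16-25 helical).
helix_loop_helix <- function() {
  phis <- c(rep(-57, 10), rep(-120, 5), rep(-57, 10))
  psis <- c(rep(-47, 10), rep(120, 5), rep(-47, 10))
  new_structure(build_chain(phis, psis))
}

# Adversarial counterexample: side-chain atoms touch at <= 4 A while the
# CB-CB distance exceeds the 8 A prefilter, so only the exhaustive route
# finds the pair.
long_sidechain_counterexample <- function() {
  binder <- tibble::tibble(
    chain = "B", resid = 10L, resname = "ARG",
    atom = c("N", "CA", "C", "CB", "CG", "CD", "NE"),
    x = c(-1.4, 0, 1.2, 0, 0.3, 0, 0),
    y = c(0.6, 0, 0.8, -1.4, -2.7, -3.6, -4.5), z = 0
  )
  # side chains reach towards each other: NE-OD1 = 3.5 A, CB-CB = 8.6 A
  receptor <- tibble::tibble(
    chain = "A", resid = 340L, resname = "ASP",
    atom = c("N", "CA", "C", "CB", "CG", "OD1"),
    x = c(-1.4, 0, 1.2, 0, 0.3, 0),
    y = c(-12.6, -12, -12.8, -10, -9.0, -8.0), z = 0
  )
  new_structure(dplyr::bind_rows(receptor, binder), receptor_chain = "A")
}
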