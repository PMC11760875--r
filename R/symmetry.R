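# Object-symmetry decomposition. A ceratomyxid spore in sutural view has
# object symmetry: the suture line is the bilateral symmetry axis and the
# two shell valves are connected mirror images. The shape tangent space
# therefore splits into two orthogonal complementary subspaces - completely
# symmetric variation (among spores) and totally asymmetric variation
# (between the valves of a spore). The decomposition below follows the
# standard construction: a joint GPA of the original configurations and
# their reflected-and-relabelled copies, followed by projection onto the
# +1/-1 eigenspaces of the reflection-relabelling operator.

#' Reflect and relabel a configuration
#'
#' Reflects a configuration about a fixed axis (negating x) and swaps the
#' paired landmark labels (L2<->L8, L3<->L7, L4<->L6; L1 and L5 fixed).
#' Applying the operation twice returns the original configuration. The
#' choice of reflection axis is arbitrary: the subsequent joint GPA removes
#' it.
#'
#' @param config 8 x 2 landmark matrix.
#' @return The reflected, relabelled 8 x 2 matrix.
#' @export
#' @examples
#' o <- make_mean_outline(crescent_params(10.4, 1.75, 4.3), 400)
#' cfg <- construct_landmarks(o)
#' max(abs(reflect_relabel(reflect_relabel(cfg)) - cfg))  # 0: involution
reflect_relabel <- function(config) {
  check_config(config)
  if (nrow(config) != 8L) stop_cm("config must have exactly 8 landmarks")
  out <- config
  out[, 1] <- -out[, 1]
  out <- out[landmark_pairing()$relabel, , drop = FALSE]
  rownames(out) <- LM_LABELS
  out
}

# the reflect-relabel operator as an orthogonal 16 x 16 matrix acting on
# landmark-major flattened coordinates (x1, y1, ..., x8, y8)
reflection_operator <- function() {
  perm <- landmark_pairing()$relabel
  P <- matrix(0, 16L, 16L)
  for (j in 1:8) {
    P[2L * j - 1L, 2L * perm[j] - 1L] <- -1  # x picks -x of the partner
    P[2L * j, 2L * perm[j]] <- 1             # y picks  y of the partner
  }
  P
}

#' Decompose shape variation into symmetric and asymmetric components
#'
#' Performs the object-symmetry decomposition: digitization replicates are
#' averaged per specimen, a joint GPA is run over the originals and their
#' reflected-relabelled copies, the consensus is symmetrized, and each
#' specimen's tangent-space deviation is projected onto the symmetric
#' (reflection-invariant) and asymmetric (reflection-antisymmetric)
#' subspaces. Because the two subspaces are orthogonal complements, the sum
#' of the two sums of squares equals the total tangent sum of squares to
#' machine precision.
#'
#' @param dataset A `landmark_dataset` (replicates are averaged first) or a
#'   `gpa`-compatible input of single configurations.
#' @return Object of class `symmetry_decomposition`: per-specimen
#'   `symmetric_coords` and `asymmetric_coords` (n x 8 x 2 arrays, Procrustes
#'   frame), `ss_symmetric`, `ss_asymmetric`, `ss_total`, `pct_symmetric`,
#'   `pct_asymmetric`, the symmetrized `consensus`, the underlying joint
#'   `gpa` result, and `symmetric_tangent` (n x 16 matrix, the symmetric
#'   component used as ANCOVA response).
#' @export
decompose_symmetry <- function(dataset) {
  if (inherits(dataset, "landmark_dataset")) {
    ds <- average_replicates(dataset)
    configs <- ds$coords[, 1L, , , drop = TRUE]
    if (length(dim(configs)) == 2L) configs <- array(configs, c(1L, dim(configs)))
    host <- ds$host_id
  } else {
    Z <- configs_to_complex(dataset)
    configs <- array(NA_real_, c(nrow(Z), ncol(Z), 2L))
    configs[, , 1] <- Re(Z); configs[, , 2] <- Im(Z)
    host <- NULL
  }
  n <- dim(configs)[1]
  if (n < 2L) stop_cm("need at least 2 specimens")
  both <- array(NA_real_, c(2L * n, 8L, 2L))
  both[seq_len(n), , ] <- configs
  for (i in seq_len(n)) both[n + i, , ] <- reflect_relabel(configs[i, , ])
  g <- gpa(both)

  P <- reflection_operator()
  # symmetrized consensus: average of the consensus and its reflection
  cons <- as.numeric(t(g$consensus))             # landmark-major flatten
  cons_s <- (cons + as.numeric(P %*% cons)) / 2
  cons_mat <- unflatten_config(cons_s)
  cons_mat <- sweep(cons_mat, 2L, colMeans(cons_mat))
  cons_s <- as.numeric(t(cons_mat))
  cons_s <- cons_s / sqrt(sum(cons_s^2))

  # tangent residuals of the original configurations about the symmetric
  # consensus (complex projection removes scale and rotation directions)
  cz <- complex(real = cons_s[seq(1, 16, 2)], imaginary = cons_s[seq(2, 16, 2)])
  Zo <- matrix(complex(real = g$aligned[seq_len(n), , 1],
                       imaginary = g$aligned[seq_len(n), , 2]), n, 8L)
  # re-align each original to the symmetric consensus
  ip <- Zo %*% Conj(cz)
  Zo <- Zo * as.vector(Conj(ip) / Mod(ip))
  coef <- Zo %*% Conj(cz)
  tang <- Zo - as.vector(coef) %*% t(cz)
  X <- flatten_configs(tang)                     # tangent deviations from consensus

  sym <- (X + X %*% t(P)) / 2
  asym <- (X - X %*% t(P)) / 2
  ss_sym <- sum(sym^2); ss_asym <- sum(asym^2); ss_tot <- sum(X^2)

  to_array <- function(M, add_consensus = TRUE) {
    a <- array(NA_real_, c(n, 8L, 2L), dimnames = list(NULL, LM_LABELS, c("x", "y")))
    for (i in seq_len(n)) {
      cfg <- unflatten_config(M[i, ] + if (add_consensus) cons_s else 0)
      a[i, , ] <- cfg
    }
    a
  }
  res <- list(
    symmetric_coords = to_array(sym, TRUE),
    asymmetric_coords = to_array(asym, FALSE),
    ss_symmetric = ss_sym, ss_asymmetric = ss_asym, ss_total = ss_tot,
    pct_symmetric = 100 * ss_sym / ss_tot,
    pct_asymmetric = 100 * ss_asym / ss_tot,
    consensus = unflatten_config(cons_s),
    symmetric_tangent = sym,
    host_id = host, gpa = g
  )
  class(res) <- "symmetry_decomposition"
  res
}

#' @export
print.symmetry_decomposition <- function(x, ...) {
  cat("Object-symmetry decomposition\n")
  cat(sprintf("  symmetric  component: %6.2f %% of total shape variance\n",
              x$pct_symmetric))
  cat(sprintf("  asymmetric component: %6.2f %% of total shape variance\n",
              x$pct_asymmetric))
  invisible(x)
}
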