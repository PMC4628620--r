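# Independent oracles used to cross-check the analytic implementations.

# Gene-dropping estimate of pairwise kinship: founder alleles are uniquely
# labelled, dropped down the pedigree for `ndrops` unlinked loci, and
# phi_ij is estimated as the probability that a random allele from i and a
# random allele from j are identical by descent.
ibd_drop_phi <- function(ped, ndrops = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  fi <- unname(idx[ped$father]); mi <- unname(idx[ped$mother])
  H1 <- matrix(0L, n, ndrops); H2 <- matrix(0L, n, ndrops)
  lab <- 0L
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      H1[i, ] <- lab + 1L; H2[i, ] <- lab + 2L; lab <- lab + 2L
    } else {
      pick <- runif(ndrops) < 0.5
      H1[i, ] <- ifelse(pick, H1[fi[i], ], H2[fi[i], ])
      pick <- runif(ndrops) < 0.5
      H2[i, ] <- ifelse(pick, H1[mi[i], ], H2[mi[i], ])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    p <- 0.25 * (rowMeans(rbind(H1[i, ] == H1[j, ], H1[i, ] == H2[j, ],
                                H2[i, ] == H1[j, ], H2[i, ] == H2[j, ])))
    phi[i, j] <- phi[j, i] <- sum(p)
  }
  phi
}

# Dense multivariate-normal log-likelihood with generic solve/determinant;
# never touches the eigen-rotated fast path.
dense_loglik <- function(y, X, A, sigma2_g, sigma2_e) {
  n <- length(y)
  V <- sigma2_g * A + sigma2_e * diag(n)
  beta <- solve(crossprod(X, solve(V, X)), crossprod(X, solve(V, y)))
  r <- y - as.vector(X %*% beta)
  -0.5 * (n * log(2 * pi) + determinant(V)$modulus[1] +
            sum(r * solve(V, r)))
}

# Small fixture pedigrees -------------------------------------------------

ped_trio <- function() {
  pedigree(id = c("C", "F", "M"), father = c("F", "0", "0"),
           mother = c("M", "0", "0"), sex = c(1, 1, 2))
}

# two full sibs and their parents
ped_sibs <- function() {
  pedigree(id = c("F", "M", "S1", "S2"),
           father = c("0", "0", "F", "F"),
           mother = c("0", "0", "M", "M"),
           sex = c(1, 2, 1, 2))
}

# first-cousin mating: grandparents GP1 x GP2, sibs A and B marry in C and D,
# their children X and Y are first cousins and mate, producing Z (F = 1/16)
ped_cousin_child <- function() {
  pedigree(
    id     = c("GP1", "GP2", "A", "B", "C", "D", "X", "Y", "Z"),
    father = c("0",  "0",  "GP1", "GP1", "0", "0", "A", "B", "X"),
    mother = c("0",  "0",  "GP2", "GP2", "0", "0", "C", "D", "Y"),
    sex    = c(1, 2, 1, 1, 2, 2, 1, 2, 1))
}

small_random_ped <- function(seed, n_founders = 6, n_generations = 3,
                             mean_offspring = 1.8) {
  simulate_pedigree(n_founders = n_founders, n_generations = n_generations,
                    mean_offspring = mean_offspring, consanguinity_rate = 0.2,
                    immigrant_rate = 0.3, seed = seed)
}

# shared medium pedigree + eigendecomposition, built once per test run
shared_ped_env <- new.env()
get_shared_ped <- function() {
  if (is.null(shared_ped_env$ped)) {
    shared_ped_env$ped <- simulate_pedigree(
      n_founders = 40, n_generations = 4, mean_offspring = 2.4,
      consanguinity_rate = 0.05, immigrant_rate = 0.3, seed = 424)
    shared_ped_env$kin <- kinship(shared_ped_env$ped)
    shared_ped_env$eig <- kinship_eigen(shared_ped_env$kin)
  }
  shared_ped_env
}
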