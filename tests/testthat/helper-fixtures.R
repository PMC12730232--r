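# Shared fixtures and independent oracles for the test suite.

# Independent brute-force mass constructor: assembles each lipid from its
# building blocks (glycerol or sphingoid backbone, phosphate, headgroup
# alcohol, free fatty acids) with one condensation water removed per bond,
# without touching the package's class composition rules. The sum of k
# free fatty acids with n total carbons and d total double bonds is
# C_n H_(2n-2d) O_(2k) regardless of how the chains are split, so the
# lumped form is exact.
oracle_species_mass <- function(class_code, n, d, ether = 0L,
                                extra_oxygens = 0L) {
  em <- simslipid::element_masses()
  H <- em[["H"]]; O <- em[["O"]]; C <- em[["C"]]
  N <- em[["N"]]; P <- em[["P"]]; S <- em[["S"]]
  water <- 2 * H + O
  glycerol <- 3 * C + 8 * H + 3 * O
  phosphoric <- 3 * H + P + 4 * O
  head_alcohol <- c(
    PC = 5 * C + 13 * H + N + O,      # choline
    PE = 2 * C + 7 * H + N + O,       # ethanolamine
    PS = 3 * C + 7 * H + N + 3 * O,   # serine
    PG = glycerol,
    PI = 6 * C + 12 * H + 6 * O       # inositol
  )
  chains <- function(k) n * C + (2 * n - 2 * d) * H + 2 * k * O
  ether_adj <- ether * (2 * H - O)    # alkyl ether replaces acyl ester
  extra <- extra_oxygens * O

  if (class_code == "FA") return(chains(1) + extra)
  if (class_code %in% c("MG", "DG", "TG")) {
    k <- match(class_code, c("MG", "DG", "TG"))
    return(glycerol + chains(k) - k * water + ether_adj + extra)
  }
  if (class_code %in% c("Cer", "HexCer", "SHexCer", "CerPE", "SM")) {
    # sphingoid base (2 OH, amine) + amide-linked acid, lumped as above:
    # base C_c1 H_(2c1+3-2b1) N O2 plus FA minus one water
    base_mass <- n * C + (2 * n + 3 - 2 * d) * H + N + 2 * O +
      (1 * 2 * O)  # the amide acid's two oxygens before losing water
    cer <- base_mass - water
    cer <- cer + extra  # ";Ok" relative to the ;O2 baseline
    if (class_code == "Cer") return(cer)
    if (class_code == "HexCer")
      return(cer + (6 * C + 12 * H + 6 * O) - water)   # + glucose
    if (class_code == "SHexCer")
      return(cer + (6 * C + 12 * H + 6 * O) - water + S + 3 * O)
    if (class_code == "CerPE")
      return(cer + phosphoric + head_alcohol[["PE"]] - 2 * water)
    if (class_code == "SM")
      return(cer + phosphoric + head_alcohol[["PC"]] - 2 * water)
  }
  lyso <- startsWith(class_code, "L")
  base <- sub("^L", "", class_code)
  k <- if (lyso) 1L else 2L
  gpl <- glycerol + phosphoric - water + chains(k) - k * water +
    ether_adj + extra
  if (base != "PA") gpl <- gpl + head_alcohol[[base]] - water
  gpl
}

# small uniform axis fixture
tiny_axis <- function() simslipid::mass_axis(100, 110, 0.05)

# fast low-resolution simulation config for module tests
tiny_sim_config <- function(seed = 1L, ...) {
  simslipid::sim_config(nx = 32L, ny = 32L, n_cells = 3L,
                        cell_axes = c(4, 3), seed = seed, ...)
}

# Independent Mann-Whitney oracle: U from pairwise comparisons and a
# two-sided p from explicit enumeration of all group assignments, written
# without ranks so it shares no code path with the implementation.
oracle_mw <- function(x, y) {
  u_pairs <- function(a, b) {
    u <- 0
    for (ai in a) for (bj in b) u <- u + (ai > bj) + 0.5 * (ai == bj)
    u
  }
  u <- u_pairs(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx)
    u_pairs(pooled[idx], pooled[-idx]))
  p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
  list(U = u, p = p)
}

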