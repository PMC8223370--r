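#' Canned endotoxemia-like planted design
#'
#' Returns a ready-made [dyna_design()] that emulates the qualitative
#' structure of a systemic LPS challenge compared between a wild-type and a
#' receptor-null strain across seven compartments:
#'
#' * denser planted co-variation in the wild type than in the null strain in
#'   heart, liver and kidney, with the heart carrying both the largest
#'   planted network and the largest, steepest responder amplitudes;
#' * null-strain-only edge blocks in lung and spleen in the 12-24 h
#'   interval — negative associations (one shared latent factor with opposite
#'   loadings) in lung, positive ones in spleen;
#' * responder amplitudes uniformly larger in the wild type
#'   (`response_scaling` 1.0 vs 0.4);
#' * a late IL-17A/GM-CSF and IL-17A/TNF rank association in wild-type plasma
#'   and spleen only: those mediators stay at baseline through 12 h and rise
#'   (with a planted 24-48 h correlation block) afterwards, so the
#'   association is confined to the 12-48 h analysis window.
#'
#' Group sizes are 8 wild-type and 4 null animals per time point, sampled at
#' 0, 1, 4, 6, 12, 24 and 48 h.
#'
#' @param seed Seed stored in the design (used by [simulate_cohort()]).
#' @param strains Two labels: wild type first, receptor-null second.
#' @return A [dyna_design()].
#' @export
scenario_paperlike <- function(seed = 1L,
                               strains = c("C57BL/6", "TLR4-null")) {
  stopifnot(length(strains) == 2)
  wt <- strains[1]; ko <- strains[2]

  resp <- function(strain, compartment, mediators, times, effects) {
    stopifnot(length(times) == length(effects))
    keep <- effects != 0
    expand <- expand.grid(mediator = mediators, i = which(keep),
                          stringsAsFactors = FALSE)
    data.frame(strain = strain, compartment = compartment,
               mediator = expand$mediator,
               time_h = times[expand$i],
               effect_sd = effects[expand$i])
  }
  blocks <- function(strain, compartment, start_h, end_h, pairs, rho) {
    data.frame(strain = strain, compartment = compartment,
               start_h = start_h, end_h = end_h,
               mediator_a = vapply(pairs, `[`, "", 1L),
               mediator_b = vapply(pairs, `[`, "", 2L),
               rho = rho)
  }
  tp <- c(1, 4, 6, 12, 24, 48)

  heart_wt <- c("TNF", "IL-6", "MIP-1\u03b1", "IL-5", "IL-12p40",
                "IL-1\u03b2", "KC", "MCP-1", "IFN-\u03b3", "IL-10")
  plateau <- c(2, 2, 2, 2, 2, 1.5)

  responders <- rbind(
    # wild type: broad, steep response in heart; flatter elsewhere
    resp(wt, "heart", heart_wt, tp, c(1, 2.5, 3, 3, 2, 1)),
    resp(wt, "liver", c("IL-6", "KC", "MCP-1", "IL-10", "MIG", "IP-10"),
         tp, c(0.5, 1.5, 2, 2, 2.5, 1.5)),
    resp(wt, "kidney", c("IL-6", "KC", "MCP-1", "IP-10", "MIG"),
         tp, plateau),
    resp(wt, "plasma", c("IL-6", "KC", "MCP-1", "IL-10", "IP-10"),
         tp, plateau),
    resp(wt, "gut", c("IL-6", "KC", "MCP-1", "IL-10"), tp, plateau),
    resp(wt, "lung", c("IL-6", "KC", "IL-10", "IP-10"), tp, plateau),
    resp(wt, "spleen", c("IL-6", "KC"), tp, plateau),
    # wild type: late Th17-like signature in plasma and spleen only
    resp(wt, "plasma", c("IL-17A", "GM-CSF", "TNF"), tp,
         c(0, 0, 0, 0, 1.5, 2.5)),
    resp(wt, "spleen", c("IL-17A", "GM-CSF", "TNF"), tp,
         c(0, 0, 0, 0, 1.5, 2.5)),
    # null strain: weak residual responses (effects are x0.4 scaled)
    resp(ko, "heart", c("TNF", "IL-6"), tp, c(4.5, 4.5, 4.5, 4.5, 0, 0)),
    resp(ko, "liver", c("IL-6", "KC"), tp, c(5, 5, 5, 0, 0, 0)),
    resp(ko, "kidney", c("KC", "MCP-1"), tp, c(0, 5, 5, 5, 5, 0)),
    resp(ko, "plasma", c("IL-6", "KC"), tp, c(0, 5, 5, 5, 5, 0)),
    resp(ko, "gut", c("IL-6", "KC", "MCP-1"), tp, c(0, 6, 6, 6, 0, 0)),
    resp(ko, "lung", c("IL-6", "KC", "IL-10", "IP-10"), tp,
         c(0, 0, 0, 6, 6, 0)),
    resp(ko, "spleen", c("IL-6", "KC", "MCP-1", "IL-10"), tp,
         c(0, 0, 0, 6, 6, 0)))

  # lung null block: one latent factor, IL-6/KC loading +, IL-10/IP-10
  # loading -, so pairwise correlations are +-0.9 and the matrix is PSD
  lung_pairs <- list(c("IL-6", "KC"), c("IL-6", "IL-10"),
                     c("IL-6", "IP-10"), c("KC", "IL-10"),
                     c("KC", "IP-10"), c("IL-10", "IP-10"))
  lung_rho <- c(0.9, -0.9, -0.9, -0.9, -0.9, 0.9)
  spleen_pairs <- list(c("IL-6", "KC"), c("IL-6", "MCP-1"),
                       c("IL-6", "IL-10"), c("KC", "MCP-1"),
                       c("KC", "IL-10"), c("MCP-1", "IL-10"))

  # the set of pairs active at any single time point must form disjoint
  # pairs or complete cliques, otherwise the assembled correlation matrix
  # is not positive semi-definite (consecutive intervals share endpoints,
  # so blocks of adjacent intervals combine at the shared time point)
  heart_clique <- c("TNF", "IL-6", "MIP-1\u03b1", "IL-5", "IL-12p40")
  heart_pairs <- utils::combn(heart_clique, 2, simplify = FALSE)
  th17_pairs <- list(c("IL-17A", "GM-CSF"), c("IL-17A", "TNF"),
                     c("GM-CSF", "TNF"))
  th17_rho <- c(0.9, 0.9, 0.81)  # one latent factor: 0.81 = 0.9^2
  gut_ko_tri <- list(c("IL-6", "KC"), c("KC", "MCP-1"),
                     c("IL-6", "MCP-1"))

  edge_blocks <- rbind(
    # wild-type heart: densest planted network, a TNF-centred 5-mediator
    # clique sustained over 1-12 h, plus a late disjoint pair
    blocks(wt, "heart", 1, 12, heart_pairs, 0.9),
    blocks(wt, "heart", 12, 24, list(c("KC", "MCP-1")), 0.9),
    blocks(wt, "liver", 6, 12, list(c("IL-6", "MCP-1")), 0.9),
    blocks(wt, "liver", 12, 24,
           list(c("KC", "MIG"), c("IL-10", "IP-10")), 0.95),
    blocks(wt, "kidney", 6, 12, list(c("KC", "MCP-1")), 0.95),
    blocks(wt, "kidney", 12, 24, list(c("IL-6", "MIG")), 0.95),
    blocks(wt, "kidney", 24, 48, list(c("KC", "IP-10")), 0.9),
    blocks(wt, "plasma", 6, 12, list(c("IL-6", "KC")), 0.9),
    blocks(wt, "gut", 4, 6, list(c("IL-6", "KC")), 0.95),
    blocks(wt, "gut", 6, 12, list(c("MCP-1", "IL-10")), 0.9),
    blocks(wt, "lung", 6, 12, list(c("IL-6", "KC")), 0.9),
    # wild-type late Th17-like rank association, plasma and spleen
    blocks(wt, "plasma", 24, 48, th17_pairs, th17_rho),
    blocks(wt, "spleen", 24, 48, th17_pairs, th17_rho),
    # null strain: sparse except lung/spleen at 12-24 h
    blocks(ko, "heart", 4, 6, list(c("TNF", "IL-6")), 0.95),
    blocks(ko, "liver", 1, 6, list(c("IL-6", "KC")), 0.95),
    blocks(ko, "kidney", 6, 24, list(c("KC", "MCP-1")), 0.95),
    blocks(ko, "plasma", 6, 24, list(c("IL-6", "KC")), 0.95),
    blocks(ko, "gut", 4, 6, gut_ko_tri, 0.95),
    blocks(ko, "gut", 6, 12, gut_ko_tri, 0.95),
    blocks(ko, "lung", 12, 24, lung_pairs, lung_rho),
    blocks(ko, "spleen", 12, 24, spleen_pairs, 0.9))

  dyna_design(
    strains = strains,
    compartments = default_compartments(),
    time_points_h = c(0, 1, 4, 6, 12, 24, 48),
    n_per_timepoint = stats::setNames(c(8L, 4L), strains),
    response_scaling = stats::setNames(c(1, 0.4), strains),
    responders = responders,
    edge_blocks = edge_blocks,
    noise_cv = 0.3,
    seed = seed)
}
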