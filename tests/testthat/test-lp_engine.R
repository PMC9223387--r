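## FBA/pFBA core: trivial LPs, independent-oracle equivalence, and the
## LP-theory properties every optimal solution must satisfy.

chain_model <- function(uptake_bound = 10) {
  mets <- data.frame(id = c("a_e", "a_c", "b_c"),
                     name = c("a", "a", "b"),
                     compartment = c("e", "c", "c"))
  rxns <- list(
    list(id = "EX_a_e", name = "a exchange", stoichiometry = c(a_e = -1),
         lower_bound = -uptake_bound, upper_bound = 0, gpr = "",
         kind = "exchange"),
    list(id = "T_a", name = "a transport",
         stoichiometry = c(a_e = -1, a_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "", kind = "transport"),
    list(id = "CONV", name = "a to b", stoichiometry = c(a_c = -1, b_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "", kind = "internal"),
    list(id = "GROWTH", name = "sink", stoichiometry = c(b_c = -1),
         lower_bound = 0, upper_bound = 1000, gpr = "",
         kind = "sink_demand"))
  metabolic_model("chain", c(e = "extracellular", c = "cytosol"),
                  mets, rxns, objective = c(GROWTH = 1))
}

test_that("a linear chain with bounded uptake grows at the uptake bound", {
  m <- chain_model(10)
  sol <- fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  ## closing the uptake kills growth
  sol0 <- fba(set_bounds(m, "EX_a_e", lower = 0))
  expect_equal(sol0$objective_value, 0, tolerance = 1e-9)
})

test_that("FBA matches the independent LP oracle on generated networks", {
  specs <- list(toy_model_spec(),
                toy_model_spec(include_anaerobic_route = FALSE),
                toy_model_spec(n_essential_aa = 6, n_nonessential_aa = 5),
                toy_model_spec(include_urea_route = FALSE))
  for (sp in specs) {
    m <- generate_toy_model(sp)
    mine <- fba(m)
    orac <- oracle_fba_objective(m)
    expect_false(is.null(orac))
    expect_equal(mine$objective_value, orac$objective, tolerance = 1e-6)
  }
})

test_that("pFBA routes all flux through the shorter of two parallel paths", {
  mets <- data.frame(id = c("a_e", "a_c", "m_c", "b_c"),
                     name = c("a", "a", "m", "b"),
                     compartment = c("e", "c", "c", "c"))
  rxns <- list(
    list(id = "EX_a_e", name = "x", stoichiometry = c(a_e = -1),
         lower_bound = -10, upper_bound = 0, gpr = "", kind = "exchange"),
    list(id = "T_a", name = "x", stoichiometry = c(a_e = -1, a_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "", kind = "transport"),
    list(id = "SHORT", name = "x", stoichiometry = c(a_c = -1, b_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "", kind = "internal"),
    list(id = "LONG1", name = "x", stoichiometry = c(a_c = -1, m_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "", kind = "internal"),
    list(id = "LONG2", name = "x", stoichiometry = c(m_c = -1, b_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "", kind = "internal"),
    list(id = "GROWTH", name = "x", stoichiometry = c(b_c = -1),
         lower_bound = 0, upper_bound = 1000, gpr = "",
         kind = "sink_demand"))
  m <- metabolic_model("par", c(e = "extracellular", c = "cytosol"),
                       mets, rxns, objective = c(GROWTH = 1))
  sol <- pfba(m)
  expect_equal(sol$objective_value, 10, tolerance = 1e-8)
  expect_equal(unname(sol$fluxes[["SHORT"]]), 10, tolerance = 1e-8)
  expect_equal(unname(sol$fluxes[["LONG1"]]), 0, tolerance = 1e-8)
  ## hand-enumerated minimum: 10 (uptake) + 10 (transport) + 10 (short)
  ## + 10 (growth) = 40; the long route would give 50
  expect_equal(sol$sum_abs_flux, 40, tolerance = 1e-8)
})

test_that("pFBA preserves growth and can only shrink total flux", {
  m <- toy_default()
  f <- fba(m)
  p <- pfba(m)
  expect_equal(p$objective_value, f$objective_value, tolerance = 1e-7)
  expect_lte(p$sum_abs_flux, sum(abs(f$fluxes)) + 1e-6)
  ## matches the independently built split-variable oracle
  orac <- oracle_pfba_sumabs(m, f$objective_value)
  expect_false(is.null(orac))
  expect_equal(p$sum_abs_flux, orac, tolerance = 1e-5)
})

test_that("optimal solutions satisfy mass balance and complementarity", {
  m <- toy_default()
  sol <- fba(m)
  expect_lt(mass_balance_residual(m, sol), 1e-6)
  b <- reaction_bounds(m)
  v <- sol$fluxes[b$reaction]
  interior <- v > b$lower_bound + 1e-6 & v < b$upper_bound - 1e-6
  expect_true(all(abs(sol$reduced_costs[b$reaction][interior]) < 1e-6))
})

test_that("the FBA optimum scales linearly with all bounds", {
  m <- toy_default()
  base <- fba(m)$objective_value
  for (cc in c(0.5, 2)) {
    m2 <- m
    for (id in names(m2$reactions)) {
      m2$reactions[[id]]$lower_bound <- cc * m2$reactions[[id]]$lower_bound
      m2$reactions[[id]]$upper_bound <- cc * m2$reactions[[id]]$upper_bound
    }
    expect_equal(fba(m2)$objective_value, cc * base, tolerance = 1e-6)
  }
})

test_that("oxygen reference matches a two-stage oracle computation", {
  m <- toy_aerobe()
  oref <- oxygen_reference(m)
  m2 <- set_bounds(m, "EX_o2_e", lower = -1e6)
  orac1 <- oracle_fba_objective(m2)
  expect_equal(oref$mu_max, orac1$objective, tolerance = 1e-6)
  ## oracle stage 2: minimize O2 import at fixed maximal growth
  S <- stoichiometric_matrix(m2)
  lb <- vapply(m2$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(m2$reactions, `[[`, 0, "upper_bound")
  grow <- stats::setNames(numeric(ncol(S)), colnames(S))
  grow[names(m2$objective)] <- m2$objective
  S2 <- rbind(S, grow)
  o2col <- stats::setNames(numeric(ncol(S)), colnames(S))
  o2col[["EX_o2_e"]] <- 1
  orac2 <- oracle_lp(o2col, S2, lb, ub, maximize = TRUE,
                     rhs = c(rep(0, nrow(S)), oref$mu_max))
  expect_equal(oref$r_max, -orac2$objective, tolerance = 1e-4)
  ## more feed never hurts: relaxing uptake bounds is a relaxation
  m3 <- set_bounds(m, names(exchange_metabolites(m)), lower = -2000)
  expect_gte(oxygen_reference(m3)$mu_max, oref$mu_max - 1e-6)
})

test_that("a model that grows without oxygen has r_max = 0", {
  m <- chain_model(5)  # no oxygen anywhere
  mets <- m$metabolites
  mets <- rbind(mets, data.frame(id = "o2_e", name = "o2",
                                 compartment = "e",
                                 formula = NA_character_,
                                 molar_mass = NA_real_))
  rxns <- m$reactions
  rxns[["EX_o2_e"]] <- list(id = "EX_o2_e", name = "o2 exchange",
                            stoichiometry = c(o2_e = -1),
                            lower_bound = -1000, upper_bound = 1000,
                            gpr = "", kind = "exchange")
  m2 <- metabolic_model("anaerobe", m$compartments, mets, rxns,
                        objective = m$objective)
  oref <- oxygen_reference(m2)
  expect_gt(oref$mu_max, 0)
  expect_equal(oref$r_max, 0, tolerance = 1e-8)
})

test_that("infeasible and unbounded problems are reported, not hidden", {
  res <- lp_solve(c(1, 0), matrix(c(1, 1), 1, 2), 5, "=",
                  lb = c(0, 0), ub = c(1, 1))
  expect_equal(res$status, "infeasible")
  res2 <- lp_solve(c(1, 0), matrix(c(1, -1), 1, 2), 0, "=",
                   lb = c(-Inf, -Inf), ub = c(Inf, Inf), maximize = TRUE)
  expect_equal(res2$status, "unbounded")
})
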