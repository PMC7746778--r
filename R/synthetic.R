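#' Generate a random reference relationship graph
#'
#' Builds a random [ReferenceMap-class] for simulation studies: a bipartite
#' function-to-reaction graph over a reaction-to-compound graph with signed
#' stoichiometric coefficients. A stated fraction of functions reach their
#' reactions only through EC numbers (exercising the enzyme-number fallback
#' route), a stated fraction are transporters with direct compound links,
#' and the chemical dictionary is padded with 20% decoy compounds never
#' linked to any function, so random coverage draws include unlinkable
#' compounds -- mirroring a real chemical dictionary, which is far larger
#' than the linkable compound set.
#'
#' @param nKo,nRxn,nCpd graph sizes (all positive).
#' @param edgeDensity expected fraction of reactions each ordinary function
#'   links to (at least one edge is guaranteed).
#' @param fracEcOnly fraction of non-transporter functions whose reactions
#'   are reachable only via EC numbers.
#' @param fracTransporter fraction of functions that are transporters.
#' @param seed integer seed; identical parameters and seed give identical
#'   maps.
#' @return A [ReferenceMap-class].
#' @export
makeReference <- function(nKo = 60, nRxn = 60, nCpd = 150, edgeDensity = 0.05,
                          fracEcOnly = 0.15, fracTransporter = 0.10,
                          seed = 1) {
  stopifnot(nKo >= 1, nRxn >= 1, nCpd >= 2,
            edgeDensity > 0, edgeDensity <= 1,
            fracEcOnly >= 0, fracEcOnly <= 1,
            fracTransporter >= 0, fracTransporter < 1)
  set.seed(stageSeed(seed, "make_reference"))
  kos <- sprintf("ko:K%05d", seq_len(nKo))
  rxns <- sprintf("rxn:R%05d", seq_len(nRxn))
  cpds <- sprintf("cpd:C%05d", seq_len(nCpd))

  ## reactions: 2-5 compounds each, signed coefficients (some magnitude 2)
  rxnToCpd <- lapply(rxns, function(r) {
    k <- sample(2:min(5, nCpd), 1)
    chosen <- sample(cpds, k)
    coef <- sample(c(-2, -1, 1, 2), k, replace = TRUE,
                   prob = c(0.1, 0.4, 0.4, 0.1))
    setNames(coef, chosen)[order(chosen)]
  })
  names(rxnToCpd) <- rxns

  n_tr <- round(nKo * fracTransporter)
  transporters <- if (n_tr) sample(kos, n_tr) else character(0)
  enzymatic <- setdiff(kos, transporters)
  n_ec <- round(length(enzymatic) * fracEcOnly)
  ec_only <- if (n_ec) sample(enzymatic, n_ec) else character(0)
  direct <- setdiff(enzymatic, ec_only)

  draw_rxns <- function() {
    k <- max(1, rbinom(1, nRxn, edgeDensity))
    sort(sample(rxns, k))
  }
  koToRxn <- setNames(lapply(direct, function(f) draw_rxns()), direct)

  ## EC-only functions: a private EC number per function, mapped to reactions
  ecs <- sprintf("ec:%d.%d.%d.%d", sample(1:6, max(n_ec, 0), TRUE),
                 sample(1:20, max(n_ec, 0), TRUE),
                 sample(1:20, max(n_ec, 0), TRUE), seq_len(max(n_ec, 0)))
  koToEc <- setNames(lapply(seq_len(n_ec), function(i) ecs[i]), ec_only)
  ecToRxn <- setNames(lapply(seq_len(n_ec), function(i) draw_rxns()), ecs)

  transporterToCpd <- setNames(
    lapply(transporters, function(f) sort(sample(cpds, sample(1:3, 1)))),
    transporters)

  decoys <- sprintf("cpd:D%05d", seq_len(ceiling(nCpd * 0.2)))
  new("ReferenceMap",
      koToRxn = koToRxn,
      koToEc = if (n_ec) koToEc else structure(list(), names = character(0)),
      ecToRxn = if (n_ec) ecToRxn else structure(list(), names = character(0)),
      rxnToCpd = rxnToCpd,
      transporterToCpd = if (n_tr) transporterToCpd else
        structure(list(), names = character(0)),
      dictionary = sort(c(cpds, decoys)),
      orphanRxns = character(0))
}

#' Simulate a paired multi-study case/control cohort
#'
#' Generates paired function and metabolite tables with known ground truth,
#' emulating the statistical structure of paired microbiome-metabolome
#' cohorts: overdispersed function counts (negative binomial around
#' per-function lognormal baselines with lognormal per-sample library
#' sizes), a planted case/control fold change on a subset of linked
#' functions, metabolite abundances as noisy weighted sums of the relative
#' abundances of their linked functions (multiplicative lognormal noise),
#' a fraction of host-derived metabolites independent of any function, and
#' partial metabolome detection: the measured panel is a random
#' `detectFrac` subset of the chemical dictionary (compound-level censoring
#' emulating untargeted-coverage limits), with low intensities truncated to
#' zero so prevalence filters are exercised.
#'
#' @param ref a [ReferenceMap-class], typically from [makeReference()].
#' @param nCase,nCtrl samples per group, split evenly across studies.
#' @param nStudies number of study blocks.
#' @param nPlanted number of linked functions given the fold change.
#' @param foldChange multiplicative case effect on planted functions
#'   (1 = null cohort).
#' @param noiseSd lognormal noise sd on metabolite abundances.
#' @param detectFrac fraction of the dictionary on the measured panel.
#' @param hostFrac fraction of panel compounds given independent
#'   host-derived abundances even when linked.
#' @param dispersion negative-binomial dispersion (1/size) of counts.
#' @param seed integer seed.
#' @return List: `funcs` and `metab` ([AbundanceTable-class] with `group`
#'   and `study` metadata) and `truth` (planted functions, fold change,
#'   truly differential compounds, weight matrix, detection mask,
#'   generator parameters).
#' @export
simulatePairedCohort <- function(ref, nCase = 30, nCtrl = 30, nStudies = 2,
                                 nPlanted = 5, foldChange = 8, noiseSd = 0.3,
                                 detectFrac = 0.6, hostFrac = 0.15,
                                 dispersion = 0.3, seed = 1) {
  stopifnot(is(ref, "ReferenceMap"), nCase >= 2, nCtrl >= 2, nStudies >= 1,
            foldChange > 0, noiseSd >= 0, detectFrac > 0, detectFrac <= 1,
            hostFrac >= 0, hostFrac <= 1, dispersion > 0)
  set.seed(stageSeed(seed, "simulate_cohort"))

  funs <- sort(unique(c(names(ref@koToRxn), names(ref@koToEc),
                        names(ref@transporterToCpd))))
  linked <- funs[vapply(funs, function(f)
    length(compoundsForFunction(ref, f)) > 0, logical(1))]
  if (nPlanted > length(linked))
    stop("nPlanted exceeds the number of linked functions (", length(linked), ")")

  n <- nCase + nCtrl
  samples <- sprintf("S%03d", seq_len(n))
  group <- c(rep("case", nCase), rep("control", nCtrl))
  ## interleave groups across study blocks so every study has both
  study <- sprintf("study%d", 1 + (seq_len(n) %% nStudies))
  planted <- if (nPlanted) sort(sample(linked, nPlanted)) else character(0)

  ## function counts: NB around lognormal baselines, lognormal library sizes
  base <- rlnorm(length(funs), meanlog = 3, sdlog = 1.8)
  names(base) <- funs
  libsize <- rlnorm(n, meanlog = 0, sdlog = 0.25)
  mu <- outer(base, libsize)
  if (length(planted) && foldChange != 1)
    mu[planted, group == "case"] <- mu[planted, group == "case"] * foldChange
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow(mu), ncol(mu), dimnames = list(funs, samples))
  funcs <- AbundanceTable(counts, group = group, study = study)

  ## metabolite latents: weighted sums of library-size-normalized function
  ## activity (absolute, not compositional, so a planted fold change
  ## propagates only to the metabolites its functions link to)
  relab <- sweep(counts, 2, libsize, "/")
  linked_cpds <- sort(unique(unlist(lapply(funs, compoundsForFunction,
                                           ref = ref), use.names = FALSE)))
  W <- matrix(0, length(linked_cpds), length(funs),
              dimnames = list(linked_cpds, funs))
  for (f in funs) {
    cc <- compoundsForFunction(ref, f)
    if (length(cc)) W[cc, f] <- runif(length(cc), 0.5, 1.5)
  }

  dict <- chemicalDictionary(ref)
  panel <- sort(sample(dict, ceiling(detectFrac * length(dict))))
  host <- sort(sample(panel, round(hostFrac * length(panel))))
  latent <- matrix(0, length(panel), n, dimnames = list(panel, samples))
  on_panel_linked <- setdiff(intersect(panel, linked_cpds), host)
  if (length(on_panel_linked))
    latent[on_panel_linked, ] <-
      W[on_panel_linked, , drop = FALSE] %*% relab
  ## host-derived and unlinked panel compounds: independent lognormal with
  ## per-compound baselines spanning the detection limit, so some compounds
  ## are rare and the prevalence filters are exercised
  unlinked <- setdiff(panel, on_panel_linked)
  if (length(unlinked)) {
    base_u <- rnorm(length(unlinked), mean = 2, sd = 2.5)
    latent[unlinked, ] <- exp(base_u +
      matrix(rnorm(length(unlinked) * n, 0, 1), length(unlinked), n))
  }
  if (noiseSd > 0)
    latent <- latent * matrix(rlnorm(length(latent), 0, noiseSd),
                              nrow(latent), ncol(latent))
  ## detection floor: weakest intensities truncate to zero
  floor_at <- quantile(latent[latent > 0], 0.10)
  latent[latent < floor_at] <- 0
  metab <- AbundanceTable(latent, group = group, study = study)

  truly_diff <- intersect(compoundsForFunctions(ref, planted), linked_cpds)
  truth <- list(planted_functions = planted, fold_change = foldChange,
                truly_differential_compounds = truly_diff,
                weights = W, detection_mask = panel,
                host_compounds = host,
                params = list(nCase = nCase, nCtrl = nCtrl,
                              nStudies = nStudies, nPlanted = nPlanted,
                              foldChange = foldChange, noiseSd = noiseSd,
                              detectFrac = detectFrac, hostFrac = hostFrac,
                              dispersion = dispersion, seed = seed))
  list(funcs = funcs, metab = metab, truth = truth)
}

#' Worked-example reference fixture
#'
#' A tiny [ReferenceMap-class] encoding the two canonical linkage examples:
#' K24443 with two direct reactions (R02428, R02526) producing or consuming
#' C02753, C00001, C00502, C01114 and C00545; and K00046, which has no
#' direct reaction but carries EC 1.1.1.69, reaching R01738 and R01740 and
#' through them C00257, C00003, C01062, C00004, C00080, C00006 and C00005
#' -- the enzyme-number fallback route. One synthetic transporter KO with a
#' direct compound link is included; its compound is marked synthetic by
#' its identifier.
#'
#' @return A [ReferenceMap-class].
#' @export
methodsFixture <- function() {
  records <- data.frame(
    kind = c("ko_to_rxn", "ko_to_rxn",
             "ko_to_ec", "ec_to_rxn", "ec_to_rxn",
             rep("rxn_to_cpd", 5 + 3 + 4 + 4),
             "transporter_to_cpd"),
    from = c("ko:K24443", "ko:K24443",
             "ko:K00046", "ec:1.1.1.69", "ec:1.1.1.69",
             ## R02428: oxidation of a glycol; R02526 shares three compounds
             rep("rxn:R02428", 5), rep("rxn:R02526", 3),
             rep("rxn:R01738", 4), rep("rxn:R01740", 4),
             "ko:K02025"),
    to = c("rxn:R02428", "rxn:R02526",
           "ec:1.1.1.69", "rxn:R01738", "rxn:R01740",
           "cpd:C02753", "cpd:C00001", "cpd:C00502", "cpd:C01114",
           "cpd:C00545",
           "cpd:C02753", "cpd:C00001", "cpd:C00502",
           "cpd:C00257", "cpd:C00003", "cpd:C01062", "cpd:C00004",
           "cpd:C00257", "cpd:C00080", "cpd:C00006", "cpd:C00005",
           "cpd:SYN0001"),
    coef = c(rep(NA, 5),
             -1, 1, 1, -1, 1,
             -1, 1, 1,
             -1, -1, 1, 1,
             -1, 1, -1, 1,
             NA),
    stringsAsFactors = FALSE)
  buildRelationshipTable(records)
}
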