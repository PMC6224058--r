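## Synthetic sward trials with full ground truth.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: two founder ryegrass cultivars with shared and cultivar-private
## polymorphisms, mixed plots whose cultivar proportion w drifts over years
## on the logit scale, 40-plant Hardy-Weinberg sampling per plot-year,
## equal-tissue pooling, negative-binomial read depth and binomial read
## sampling with a symmetric sequencing error rate.
##
## All randomness flows from one master seed; each stage uses a documented
## substream (cultivars +0, trial +1, yield +2) so stages are reproducible
## in isolation.

#' Configuration of a synthetic sward trial
#'
#' Collects and validates every generator parameter.
#'
#' @param n_loci number of GBS SNP loci to simulate.
#' @param founders named vector: diploid founder components per cultivar.
#'   Merks was bred from a three-component polycross, Meloni from a pair
#'   cross, so the defaults are 3 and 2; cultivar allele frequencies are
#'   multiples of `1/(2*founders)` and the larger founder base gives Merks
#'   the higher expected heterozygosity.
#' @param private_fraction named vector: fraction of loci designated private
#'   to each cultivar (polymorphic there, absent from the other). Defaults
#'   1.1\% (Merks) and 2.8\% (Meloni), the proportions observed among the
#'   trial's filtered SNPs.
#' @param trajectory list describing the Merks proportion `w` in mixed plots
#'   (compositions 5-7): `year_logit` (per-year logit-scale level, default
#'   the non-monotone `qlogis(c(0.6, 0.4, 0.4, 0.6))` — Merks more prominent
#'   in years 1 and 4), `composition_logit` (per-composition offset, default
#'   0) and `plot_sd` (logit-scale plot-year noise, default 0.15).
#' @param selection `NULL` (neutral trial) or `list(n_loci =, shift_per_year
#'   =)`: that many loci receive a deterministic additive allele-frequency
#'   shift of `shift_per_year * (year - 1)`, shared by all plots — exactly
#'   the composition-consistent temporal signal the selection scan targets.
#'   Selected loci are drawn among loci segregating at intermediate
#'   frequency (both cultivar AFs in `[0.2, 0.5]`) so the full trajectory
#'   stays inside `[0, 1]`.
#' @param n_plants plants sampled per plot-year (default 40).
#' @param depth_mean,depth_dispersion negative-binomial read-depth model per
#'   locus x sample (mean and size; Poisson is the `size -> Inf` limit).
#'   Default mean 100, size 20: moderate overdispersion with rare dropout
#'   below the 30x analysis threshold, emulating the consistently covered,
#'   low-missingness locus set the trial's complete-data analysis relies
#'   on.
#' @param error_rate symmetric per-read sequencing error probability
#'   (default 0.001).
#' @param seed master seed.
#' @return a validated list of class `SimulationConfig`.
#' @export
#' @examples
#' cfg <- simulationConfig(n_loci = 500, seed = 7)
simulationConfig <- function(n_loci = 5000,
                             founders = c(merks = 3, meloni = 2),
                             private_fraction = c(merks = 0.011,
                                                  meloni = 0.028),
                             trajectory = list(
                                 year_logit = qlogis(c(0.6, 0.4, 0.4, 0.6)),
                                 composition_logit = c(0, 0, 0),
                                 plot_sd = 0.15),
                             selection = NULL,
                             n_plants = 40L,
                             depth_mean = 100, depth_dispersion = 20,
                             error_rate = 0.001, seed = 1L) {
    stopifnot(n_loci >= 1, all(founders >= 2), n_plants >= 1,
              depth_mean > 0, depth_dispersion > 0,
              error_rate >= 0, error_rate < 0.5)
    if (sum(private_fraction) > 1)
        stop("private locus fractions sum to more than 1")
    if (!is.null(selection))
        stopifnot(is.list(selection), selection$n_loci >= 1,
                  selection$shift_per_year > 0)
    cfg <- list(n_loci = as.integer(n_loci), founders = founders,
                private_fraction = private_fraction, trajectory = trajectory,
                selection = selection, n_plants = as.integer(n_plants),
                depth_mean = depth_mean,
                depth_dispersion = depth_dispersion,
                error_rate = error_rate, seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    cfg
}

.stageSeed <- function(seed, offset) (abs(seed) + offset) %% 2147483629L

#' Simulate the two founder cultivars
#'
#' Draws per-locus allele frequencies for a Merks-like and a Meloni-like
#' cultivar. Shared loci get an ancestral frequency `p ~ U(0.05, 0.95)` from
#' which each cultivar's `2*founders` chromosomes are sampled, so cultivar
#' AFs sit on the grid `k/(2*founders)` and are correlated between
#' cultivars. Seeded private loci (the `private_fraction` share) are fixed
#' absent (AF 0) in the other cultivar and segregate at low-to-intermediate
#' frequency in the focal one; with so few founder chromosomes, chance
#' fixation during shared-locus sampling produces additional, equally real
#' private loci, so the realized private sets are supersets of the seeded
#' ones.
#'
#' @param config a [simulationConfig()].
#' @return list of class `CultivarProfiles`: numeric AF vectors `merks` and
#'   `meloni`; integer index sets `private_merks` / `private_meloni`
#'   computed from the realized frequencies (AF > 0 in the focal cultivar,
#'   exactly 0 in the other); `seeded_merks` / `seeded_meloni`, the
#'   designated subsets controlled by `private_fraction`.
#' @export
simulateCultivars <- function(config) {
    set.seed(.stageSeed(config$seed, 0L))
    n <- config$n_loci
    cat_draw <- runif(n)
    pM <- config$private_fraction[["merks"]]
    pm <- config$private_fraction[["meloni"]]
    category <- ifelse(cat_draw < pM, "merks",
                       ifelse(cat_draw < pM + pm, "meloni", "shared"))
    chromM <- 2L * config$founders[["merks"]]
    chromm <- 2L * config$founders[["meloni"]]
    afM <- afm <- numeric(n)
    sh <- category == "shared"
    p <- runif(sum(sh), 0.05, 0.95)
    afM[sh] <- rbinom(sum(sh), chromM, p) / chromM
    afm[sh] <- rbinom(sum(sh), chromm, p) / chromm
    drawPrivate <- function(k, chrom) {
        p <- runif(k, 0.05, 0.5)
        cnt <- rbinom(k, chrom, p)
        while (any(cnt == 0))                 # condition on segregating
            cnt[cnt == 0] <- rbinom(sum(cnt == 0), chrom,
                                    p[cnt == 0])
        cnt / chrom
    }
    iM <- category == "merks"; im <- category == "meloni"
    afM[iM] <- drawPrivate(sum(iM), chromM); afm[iM] <- 0
    afm[im] <- drawPrivate(sum(im), chromm); afM[im] <- 0
    out <- list(merks = afM, meloni = afm,
                private_merks = which(afM > 0 & afm == 0),
                private_meloni = which(afm > 0 & afM == 0),
                seeded_merks = which(iM), seeded_meloni = which(im))
    class(out) <- "CultivarProfiles"
    out
}

#' Simulate a pooled-GBS sward trial
#'
#' For every sample in `design` the latent population allele frequency is
#' `w * AF_Merks + (1 - w) * AF_Meloni` plus any cumulative selection shift,
#' clipped to `[0, 1]`, where `w` is the Merks proportion (1 or 0 in
#' monoculture compositions, a noisy logit trajectory in mixtures). Forty
#' diploid plants are sampled under Hardy-Weinberg, pooled with equal
#' tissue, and sequenced: per-locus depth is negative binomial and the
#' alternative read count is `Binomial(depth, f(1-e) + (1-f)e)` with `f` the
#' pooled sample AAF and `e` the sequencing error rate.
#'
#' @param config a [simulationConfig()].
#' @param design a design table ([trialDesign()]).
#' @param genotypes character vector of sample ids for which per-plant
#'   genotype calls should also be returned (default none).
#' @param profiles optional precomputed [simulateCultivars()] result.
#' @return list with elements
#'   \item{counts}{[PoolCounts] with one column per design sample,}
#'   \item{truth}{ground-truth record: `profiles`, per-sample Merks
#'     proportion `w`, latent population AF matrix `pop_af`, realized
#'     40-plant sample AAF matrix `sample_aaf`, `selected` locus indices,}
#'   \item{genotypes}{named list of [GenotypeCalls] for the requested
#'     samples.}
#' @export
simulateTrial <- function(config, design = trialDesign(),
                          genotypes = character(), profiles = NULL) {
    if (is.null(profiles))
        profiles <- simulateCultivars(config)
    set.seed(.stageSeed(config$seed, 1L))
    n <- config$n_loci
    ns <- nrow(design)
    ## Merks proportion per sample
    w <- numeric(ns)
    traj <- config$trajectory
    for (i in seq_len(ns)) {
        comp <- design$composition[i]
        rc <- design$ryegrass_content[i]
        if (rc == "Merks") w[i] <- 1
        else if (rc == "Meloni") w[i] <- 0
        else {
            ci <- comp - 4L
            off <- if (ci >= 1 && ci <= length(traj$composition_logit))
                traj$composition_logit[ci] else 0
            w[i] <- plogis(traj$year_logit[design$year[i]] + off +
                           rnorm(1, 0, traj$plot_sd))
        }
    }
    names(w) <- design$sample_id
    pop <- outer(profiles$merks, w) + outer(profiles$meloni, 1 - w)
    ## injected selection: additive per-year shift shared by all plots
    selected <- integer(0)
    if (!is.null(config$selection)) {
        cand <- which(profiles$merks >= 0.2 & profiles$merks <= 0.5 &
                      profiles$meloni >= 0.2 & profiles$meloni <= 0.5)
        if (length(cand) < config$selection$n_loci)
            cand <- which(profiles$merks > 0 | profiles$meloni > 0)
        selected <- sort(sample(cand, config$selection$n_loci))
        shift <- config$selection$shift_per_year *
            (design$year - 1)                       # per sample
        pop[selected, ] <- pmin(1, pmax(0, pop[selected, , drop = FALSE] +
            matrix(shift, length(selected), ns, byrow = TRUE)))
    }
    ## 40-plant HWE sampling; pooled AAF = mean dose / 2
    chroms <- 2L * config$n_plants
    geno_out <- list()
    dose_sum <- matrix(rbinom(n * ns, chroms, pop), n, ns)
    for (s in intersect(genotypes, design$sample_id)) {
        j <- match(s, design$sample_id)
        doses <- matrix(rbinom(n * config$n_plants, 2L, pop[, j]),
                        n, config$n_plants)
        dose_sum[, j] <- rowSums(doses)
        colnames(doses) <- sprintf("%s_plant%02d", s,
                                   seq_len(config$n_plants))
        geno_out[[s]] <- doses
    }
    saaf <- dose_sum / chroms
    ## read sampling
    depth <- matrix(rnbinom(n * ns, mu = config$depth_mean,
                            size = config$depth_dispersion), n, ns)
    e <- config$error_rate
    alt <- matrix(rbinom(n * ns, depth, saaf * (1 - e) + (1 - saaf) * e),
                  n, ns)
    ref <- depth - alt
    dimnames(ref) <- dimnames(alt) <- list(NULL, design$sample_id)
    loci <- snpLoci(rep("chr1", n), seq_len(n),
                    rep("A", n), rep("G", n))
    counts <- PoolCounts(loci, ref = ref, alt = alt, design = design)
    dimnames(pop) <- dimnames(saaf) <- list(names(rowRanges(counts)),
                                            design$sample_id)
    genos <- lapply(geno_out, function(m)
        GenotypeCalls(loci, geno = m))
    truth <- list(profiles = profiles, w = w, pop_af = pop,
                  sample_aaf = saaf, selected = selected, config = config)
    class(truth) <- "TruthRecord"
    list(counts = counts, truth = truth, genotypes = genos)
}

#' Default fixed effects for the yield generator
#'
#' Additive effects (t/ha dry matter) on the annual plot yield, chosen to
#' echo the trial's qualitative findings: clover presence raises total
#' yield, Meloni outyields Merks, and among clover cultivars Lemmon (erect)
#' gives more total yield than Crossway (creeping).
#'
#' @param mu grand mean annual DMW (t/ha).
#' @param ryegrass named effects for the ryegrass content.
#' @param clover_presence effect of having clover in the mixture.
#' @param clover named effects of the clover cultivar content.
#' @param interaction ryegrass x clover-presence interaction effect applied
#'   to Meloni-with-clover plots (0 = purely additive).
#' @param grass_logit named logit-scale offsets of the grass fraction in
#'   mixed plots (base fraction 0.7).
#' @return list of effect settings.
#' @export
yieldEffects <- function(mu = 10,
                         ryegrass = c(Merks = 0, Meloni = 0.6, both = 0.3),
                         clover_presence = 1.5,
                         clover = c(none = 0, both = 0, Lemmon = 0.4,
                                    Crossway = -0.4),
                         interaction = 0,
                         grass_logit = c(both = 0, Lemmon = -0.3,
                                         Crossway = 0.3)) {
    list(mu = mu, ryegrass = ryegrass, clover_presence = clover_presence,
         clover = clover, interaction = interaction,
         grass_logit = grass_logit)
}

#' Simulate annual yield and botanical composition
#'
#' Generates one annual total dry-matter weight per plot-year additively
#' from the fixed effects plus Gaussian random replicate and year intercepts
#' and a residual, and splits mixed-plot yield into grass and clover by a
#' logistic fraction model (weed fraction 0). Monoculture plots are all
#' grass.
#'
#' @param design design table (one row per plot-year after dropping the
#'   duplicate year rows is not needed: [trialDesign()] rows already are
#'   plot-years).
#' @param effects a [yieldEffects()] list.
#' @param varcomp named standard deviations `replicate`, `year`, `residual`,
#'   and `fraction` (logit-scale noise of the grass fraction).
#' @param seed RNG seed.
#' @return data.frame (YieldTable): `composition`, `replicate`, `year`,
#'   `plot_id`, `dmw_total`, `grass_fraction`, `clover_fraction`,
#'   `weed_fraction`, `dmw_grass`, `dmw_clover` (t/ha).
#' @export
simulateYield <- function(design = trialDesign(), effects = yieldEffects(),
                          varcomp = c(replicate = 0.3, year = 1.5,
                                      residual = 0.5, fraction = 0.1),
                          seed = 1L) {
    stopifnot(all(varcomp >= 0))
    set.seed(.stageSeed(seed, 2L))
    reps <- sort(unique(design$replicate))
    yrs <- sort(unique(design$year))
    r_eff <- setNames(rnorm(length(reps), 0, varcomp[["replicate"]]), reps)
    y_eff <- setNames(rnorm(length(yrs), 0, varcomp[["year"]]), yrs)
    has_clover <- design$clover_content != "none"
    fixed <- effects$mu +
        effects$ryegrass[design$ryegrass_content] +
        effects$clover_presence * has_clover +
        effects$clover[design$clover_content] +
        effects$interaction *
            (design$ryegrass_content == "Meloni" & has_clover)
    total <- fixed + r_eff[design$replicate] +
        y_eff[as.character(design$year)] +
        rnorm(nrow(design), 0, varcomp[["residual"]])
    gf <- rep(1, nrow(design))
    mixed <- which(has_clover)
    gf[mixed] <- plogis(qlogis(0.7) +
        effects$grass_logit[design$clover_content[mixed]] +
        rnorm(length(mixed), 0, varcomp[["fraction"]]))
    out <- data.frame(composition = design$composition,
                      replicate = design$replicate, year = design$year,
                      plot_id = design$plot_id,
                      dmw_total = as.numeric(total),
                      grass_fraction = gf, clover_fraction = 1 - gf,
                      weed_fraction = 0,
                      stringsAsFactors = FALSE)
    out$dmw_grass <- out$dmw_total * out$grass_fraction
    out$dmw_clover <- out$dmw_total * out$clover_fraction
    rownames(out) <- NULL
    out
}
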