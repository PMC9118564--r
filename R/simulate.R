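#' @include AllClasses.R AllGenerics.R
NULL

## Truncated-normal draws by inverse-CDF on a restricted uniform; exact
## and vectorized, no rejection loop.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
    lo <- stats::pnorm((lower - mean) / sd)
    hi <- stats::pnorm((upper - mean) / sd)
    stats::qnorm(stats::runif(n, lo, hi)) * sd + mean
}

#' Configure the synthetic study generator
#'
#' Builds a validated [SyntheticConfig-class]. Defaults emulate the
#' amyloid-PET / brain-transcriptome study the pipeline is designed
#' for: an ADNI-like cohort of 971 subjects (255 CN, 296 EMCI,
#' 218 LMCI, 202 AD) with age, sex and education moments matching that
#' cohort's demographics; 180 left-hemisphere HCPMMP-style ROIs; SUVR-like
#' trait values around a baseline of 1.1 with diagnostic elevation that
#' grows monotonically over EMCI -> LMCI -> AD in a fixed set of
#' affected regions; and an AHBA-like expression matrix of 10,027 genes
#' in which a small set of planted signal genes correlates spatially
#' with the true effect profile.
#'
#' @param groupSizes Named integer, subjects per CN/EMCI/LMCI/AD group.
#' @param nRois Number of ROIs (left hemisphere).
#' @param roiLabels Optional explicit labels; default `"L_R###_ROI"`.
#' @param affectedRoiFraction Fraction of ROIs carrying diagnostic signal.
#' @param effectSizes Named numeric (`EMCI`, `LMCI`, `AD`): mean trait
#'   elevation of each case stage in affected ROIs (trait/SUVR units);
#'   must be monotone non-decreasing over the progression.
#' @param covariateEffects Named numeric slopes of age (trait/yr), sex
#'   and education (trait/yr) on the trait; nonzero by default so
#'   covariate adjustment is actually exercised.
#' @param noiseSd Residual standard deviation (trait units).
#' @param baselineMean,baselineSd Per-ROI baseline level distribution.
#' @param ageMean,ageSd Per-group age moments (years), truncated to
#'   \[55, 95\].
#' @param maleFraction Per-group probability of male sex.
#' @param educationMean,educationSd Per-group education moments (years),
#'   truncated to \[6, 20\]. Defaults use the pooled cohort moments
#'   (16.13 +/- 2.75) for every group; per-group overrides are exposed.
#' @param nGenes,nSignalGenes Total genes and planted signal genes.
#' @param signalRTarget Target spatial correlation of each signal gene
#'   with the true effect profile, in (0, 1).
#' @param expressionMissingRate Per-(gene, ROI) missingness probability.
#' @param nKnownSignalGenes,nKnownGenes Size of the synthetic
#'   disease-annotation list and how many planted signal genes it
#'   contains (the rest of the list is non-signal genes).
#' @param seed Integer seed; all generator output is a pure function of
#'   the config including this seed.
#' @return A [SyntheticConfig-class].
#' @export
#' @examples
#' cfg <- syntheticConfig(groupSizes = c(CN = 10, EMCI = 10, LMCI = 10, AD = 10),
#'                        nRois = 20, nGenes = 50, nSignalGenes = 3, seed = 7)
syntheticConfig <- function(
    groupSizes = c(CN = 255L, EMCI = 296L, LMCI = 218L, AD = 202L),
    nRois = 180L,
    roiLabels = character(0),
    affectedRoiFraction = 0.4,
    effectSizes = c(EMCI = 0.10, LMCI = 0.20, AD = 0.30),
    covariateEffects = c(age = 0.005, sex = 0.02, education = -0.002),
    noiseSd = 0.2,
    baselineMean = 1.1, baselineSd = 0.05,
    ageMean = c(CN = 76.35, EMCI = 71.78, LMCI = 74.71, AD = 75.85),
    ageSd = c(CN = 6.54, EMCI = 7.28, LMCI = 8.39, AD = 7.67),
    maleFraction = c(CN = 132 / 255, EMCI = 167 / 296,
                     LMCI = 129 / 218, AD = 123 / 202),
    educationMean = c(CN = 16.13, EMCI = 16.13, LMCI = 16.13, AD = 16.13),
    educationSd = c(CN = 2.75, EMCI = 2.75, LMCI = 2.75, AD = 2.75),
    nGenes = 10027L, nSignalGenes = 12L, signalRTarget = 0.6,
    expressionMissingRate = 0.1,
    nKnownSignalGenes = min(4L, nSignalGenes),
    nKnownGenes = min(1877L, nGenes),
    seed = 1L) {
    asInt <- function(x) {
        y <- as.integer(round(x))
        names(y) <- names(x)
        y
    }
    new("SyntheticConfig",
        groupSizes = asInt(groupSizes)[.DIAGNOSIS_LEVELS],
        nRois = as.integer(nRois), roiLabels = as.character(roiLabels),
        affectedRoiFraction = affectedRoiFraction,
        effectSizes = effectSizes[.CASE_STAGES],
        covariateEffects = covariateEffects[c("age", "sex", "education")],
        noiseSd = noiseSd, baselineMean = baselineMean,
        baselineSd = baselineSd,
        ageMean = ageMean[.DIAGNOSIS_LEVELS], ageSd = ageSd[.DIAGNOSIS_LEVELS],
        maleFraction = maleFraction[.DIAGNOSIS_LEVELS],
        educationMean = educationMean[.DIAGNOSIS_LEVELS],
        educationSd = educationSd[.DIAGNOSIS_LEVELS],
        nGenes = as.integer(nGenes), nSignalGenes = as.integer(nSignalGenes),
        signalRTarget = signalRTarget,
        expressionMissingRate = expressionMissingRate,
        nKnownSignalGenes = as.integer(nKnownSignalGenes),
        nKnownGenes = as.integer(nKnownGenes),
        seed = as.integer(seed))
}

#' Generate a synthetic phenotype and imaging cohort
#'
#' Draws per-group covariates (truncated-normal age and education,
#' Bernoulli sex) and builds the subject x ROI trait matrix as
#'
#' \deqn{y_{sj} = b_j + \delta(d_s)\, a_j \pi_j + \beta_{age} age_s +
#'   \beta_{sex} sex_s + \beta_{edu} edu_s + \epsilon_{sj}}
#'
#' where \eqn{b_j} is the ROI baseline, \eqn{\delta(d)} the stage effect
#' of subject \eqn{s}'s diagnosis, \eqn{a_j \in \{0,1\}} the affected
#' indicator, \eqn{\pi_j \in (0.5, 1]} a per-ROI effect shape, and
#' \eqn{\epsilon \sim N(0, \sigma^2)} i.i.d. noise. Identical configs
#' (including seed) give bitwise-identical output.
#'
#' @param config A [SyntheticConfig-class].
#' @return `list(cohort = ImagingCohort, truth = GroundTruth)`; the
#'   truth carries the affected ROI set and the unit-free effect profile
#'   \eqn{a_j \pi_j}.
#' @export
generateCohort <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    validObject(config)
    withr::with_seed(config@seed, {
        labels <- if (length(config@roiLabels)) config@roiLabels
                  else sprintf("L_R%03d_ROI", seq_len(config@nRois))
        R <- config@nRois
        nAff <- round(config@affectedRoiFraction * R)
        affected <- sort(sample.int(R, nAff))
        profile <- numeric(R)
        profile[affected] <- stats::runif(nAff, 0.5, 1)
        names(profile) <- labels

        gs <- config@groupSizes
        n <- sum(gs)
        dx <- factor(rep(.DIAGNOSIS_LEVELS, gs), levels = .DIAGNOSIS_LEVELS)
        gi <- as.integer(dx)
        age <- .rtruncnorm(n, config@ageMean[gi], config@ageSd[gi], 55, 95)
        sex <- as.numeric(stats::runif(n) < config@maleFraction[gi])
        edu <- .rtruncnorm(n, config@educationMean[gi],
                           config@educationSd[gi], 6, 20)

        baseline <- stats::rnorm(R, config@baselineMean, config@baselineSd)
        stageEff <- c(CN = 0, config@effectSizes)[gi]
        ce <- config@covariateEffects
        covTerm <- ce["age"] * age + ce["sex"] * sex + ce["education"] * edu
        trait <- outer(rep(1, n), baseline) +
            outer(stageEff, profile) +
            covTerm +
            matrix(stats::rnorm(n * R, 0, config@noiseSd), n, R)
        dimnames(trait) <- list(sprintf("SUBJ%04d", seq_len(n)), labels)

        ph <- data.frame(subject_id = rownames(trait),
                         diagnosis = as.character(dx),
                         age = age, sex = sex, education = edu)
        list(cohort = ImagingCohort(trait, ph),
             truth = new("GroundTruth",
                         affectedRois = labels[affected],
                         effectProfile = profile,
                         signalGenes = character(0),
                         realizedR = numeric(0),
                         knownGenes = character(0),
                         seed = config@seed))
    })
}

#' Generate a synthetic regional expression matrix
#'
#' Plants `nSignalGenes` genes whose expression maps correlate spatially
#' with the true (noiseless) per-ROI effect profile at exactly
#' `signalRTarget`: a standard-normal noise map is orthogonalized
#' against the standardized profile and the two are mixed as
#' \eqn{\rho z + \sqrt{1-\rho^2}\, e_\perp}, so the realized sample
#' correlation equals the target. All remaining genes are spatially
#' independent noise. Missing entries are then inserted uniformly at
#' random at `expressionMissingRate` (each gene keeps at least three
#' observed ROIs). A synthetic disease-annotation list containing
#' `nKnownSignalGenes` of the planted genes plus non-signal padding is
#' recorded on the returned ground truth.
#'
#' Uses its own RNG stream (`config@seed + 1`), so cohort and
#' expression generation are independently reproducible.
#'
#' @param config A [SyntheticConfig-class].
#' @param truth The [GroundTruth-class] from [generateCohort()]
#'   (carries the effect profile).
#' @return `list(expr = RegionalExpression, truth = GroundTruth)` with
#'   the truth updated with signal genes, realized correlations and the
#'   annotation list.
#' @export
generateExpression <- function(config, truth) {
    stopifnot(is(config, "SyntheticConfig"), is(truth, "GroundTruth"))
    validObject(config)
    if (config@nSignalGenes > 0L &&
        !(config@signalRTarget > 0 && config@signalRTarget < 1))
        stop("signalRTarget must lie in (0, 1)")
    z <- truth@effectProfile
    R <- length(z)
    if (config@nSignalGenes > 0L && stats::sd(z) == 0)
        stop("cannot plant signal genes: the true effect profile is constant")
    withr::with_seed(config@seed + 1L, {
        G <- config@nGenes
        genes <- sprintf("GENE%05d", seq_len(G))
        m <- matrix(stats::rnorm(G * R), G, R,
                    dimnames = list(genes, names(z)))
        sig <- sort(sample.int(G, config@nSignalGenes))
        rho <- config@signalRTarget
        if (length(sig)) {
            zc <- z - mean(z)
            zs <- zc / sqrt(sum(zc^2))
            for (i in sig) {
                e <- m[i, ] - mean(m[i, ])
                e <- e - sum(e * zs) * zs         # orthogonal to profile
                e <- e / sqrt(sum(e^2))
                m[i, ] <- rho * zs + sqrt(1 - rho^2) * e
            }
        }
        realized <- if (length(sig))
            vapply(sig, function(i) stats::cor(m[i, ], z), numeric(1))
        else numeric(0)
        names(realized) <- genes[sig]

        if (config@expressionMissingRate > 0) {
            drop <- matrix(stats::runif(G * R) < config@expressionMissingRate,
                           G, R)
            # keep >= 3 observed ROIs per gene
            short <- which(rowSums(!drop) < 3L)
            for (i in short) {
                need <- 3L - sum(!drop[i, ])
                drop[i, utils::head(which(drop[i, ]), need)] <- FALSE
            }
            m[drop] <- NA_real_
        }

        nonsig <- setdiff(seq_len(G), sig)
        known <- c(genes[utils::head(sig, config@nKnownSignalGenes)],
                   genes[sample(nonsig,
                       min(config@nKnownGenes - config@nKnownSignalGenes,
                           length(nonsig)))])
        list(expr = RegionalExpression(m),
             truth = new("GroundTruth",
                         affectedRois = truth@affectedRois,
                         effectProfile = truth@effectProfile,
                         signalGenes = genes[sig],
                         realizedR = realized,
                         knownGenes = sort(toupper(known)),
                         seed = truth@seed))
    })
}

#' Generate a full synthetic study, optionally writing the input files
#'
#' Convenience wrapper running [generateCohort()] then
#' [generateExpression()]; with `dir` set it also writes the four
#' standard inputs (`phenotypes.csv`, `imaging.csv`, `expression.tsv`,
#' `gene_set.txt`) plus a `truth.json` sidecar.
#'
#' @param config A [SyntheticConfig-class].
#' @param dir Optional output directory (created if needed).
#' @return `list(cohort, expr, truth[, files])`.
#' @export
simulateStudy <- function(config, dir = NULL) {
    co <- generateCohort(config)
    ex <- generateExpression(config, co$truth)
    out <- list(cohort = co$cohort, expr = ex$expr, truth = ex$truth)
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        files <- c(phenotypes = file.path(dir, "phenotypes.csv"),
                   imaging = file.path(dir, "imaging.csv"),
                   expression = file.path(dir, "expression.tsv"),
                   gene_set = file.path(dir, "gene_set.txt"),
                   truth = file.path(dir, "truth.json"))
        writePhenotypes(out$cohort, files["phenotypes"])
        writeImaging(out$cohort, files["imaging"])
        writeExpression(out$expr, files["expression"])
        .writeLines(out$truth@knownGenes, files["gene_set"])
        writeGroundTruth(out$truth, files["truth"])
        out$files <- files
    }
    out
}

#' Write / read a ground-truth sidecar
#'
#' JSON serialization of a [GroundTruth-class] so synthetic studies can
#' be scored after a round trip through disk.
#'
#' @param truth A [GroundTruth-class].
#' @param path JSON path.
#' @return `writeGroundTruth`: `path`, invisibly. `readGroundTruth`:
#'   a [GroundTruth-class].
#' @export
writeGroundTruth <- function(truth, path) {
    jsonlite::write_json(
        list(affected_rois = truth@affectedRois,
             effect_profile = as.list(truth@effectProfile),
             signal_genes = truth@signalGenes,
             realized_r = as.list(truth@realizedR),
             known_genes = truth@knownGenes,
             seed = truth@seed),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("GroundTruth",
        affectedRois = as.character(x$affected_rois),
        effectProfile = unlist(x$effect_profile),
        signalGenes = as.character(x$signal_genes),
        realizedR = if (length(x$realized_r)) unlist(x$realized_r)
                    else numeric(0),
        knownGenes = as.character(x$known_genes),
        seed = as.integer(x$seed))
}
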