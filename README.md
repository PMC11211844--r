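# sdlineage

Maximum-likelihood inference of **spatial cell lineage trees** from spatial
lineage tracing data — experiments that grow a cell colony from a single
progenitor while CRISPR editing writes heritable barcodes into the genome and
live imaging records each cell's 2D position. Given the (known) tree topology,
the observed barcode character matrix **S**, and the final cell locations
**L**, `sdlineage` co-estimates time-resolved branch lengths, the spatial
diffusion rate, and the barcode mutation parameters. It is written for
computational biologists analyzing imaging-based lineage tracing (e.g.
intMEMOIR-style data) and for methodologists studying phylogeographic models
of cell motility.

## The model

Cell motility follows a **symmetric-displacement (SD)** model: at each
division the two daughters are placed at $\pm r(\cos\theta_u, \sin\theta_u)$
from the parent (a fixed displacement magnitude $r$, one angle per division),
then diffuse independently by Brownian motion with rate $\sigma$ (per-axis
variance $\sigma^2\delta$ over a branch of duration $\delta$). At $r = 0$
this is the classical phylogeographic Brownian model. Leaf positions per axis
are multivariate normal with mean accumulating the signed displacements and
covariance $\Sigma(v,w) = \sigma^2\,t(\mathrm{lca}(v,w))$.

Barcodes evolve per site as an irreversible continuous-time Markov chain on
$\{0, 1..M, -1\}$: editing $0 \to a$ at rate $\lambda\pi_a$, heritable
silencing to $-1$ at rate $\nu$ from any state, and per-leaf dropout to `?`
with probability $\phi$.

The two modalities are independent given the tree, so the joint likelihood is
the product
$L(T,\Omega; \mathbf{L}, \mathbf{S}) = L_L \cdot L_S$, maximized subject to
the common-sampling-time constraint
$\sum_{\mathrm{Path}(r_T,v)} \delta_e = \tau_{end}$ for every leaf $v$.
Both likelihoods are evaluated by linear-time pruning (with dense-matrix and
enumeration oracles used in the tests), and the optimizer uses analytic
gradients. See the methods vignette
(`vignettes/sdlineage-methods.Rmd`) for the estimators, the
degrees-of-freedom-corrected $\hat\sigma$, and all numerical conventions.

## Worked example

Simulate a 20-cell colony under the default study conditions
($\sigma = 1.5$, $r = 6.68$, $K = 10$ sites, $\lambda = 0.006$/frame,
$\tau_{end} = 216$ frames), forget the branch lengths, and re-estimate
everything from the barcode matrix plus the final positions:

```r
library(sdlineage)
fx <- make_fixture(tempfile("colony"), preset = "paper-default",
                   seed = 7, n = 20)
topo <- fx$tree
topo$brlen[] <- NA                      # keep only the topology
cfg <- model_config("S+L", r = 6.68, tau_end = 216, restarts = 2,
                    seed = 1, fixed = list(nu = 0))
fit <- fit_lineage(topo, fx$matrix, fx$locations, cfg)
print(fit)
#> <sd_fit> modality SL, r = 6.68, log-likelihood -292.0936
#>   sigma = 1.5401, root = (0.272, 15.274)
#>   lambda = 0.00616, nu = 0.00000, phi = 0.0500
branch_mape(fx$tree, fit$tree)
#> [1] 0.666
```

The diffusion rate (truth 1.5) and mutation rate (truth 0.006) are recovered
closely; the branch-length mean absolute percentage error of 0.67 means the
average division time is off by about two-thirds of its true value, typical
for colonies of this size. Refitting with the displacement ignored shows the
classical misspecification bias — diffusion absorbs the division
displacement:

```r
fit0 <- fit_lineage(topo, fx$matrix, fx$locations,
                    model_config("S+L", r = 0, tau_end = 216, restarts = 2,
                                 seed = 1, fixed = list(nu = 0)))
fit0$sigma
#> [1] 1.878
```

A command-line interface wraps the same functionality:

```sh
exec/sdlineage simulate --preset paper-default --seed 1 --out colony/
exec/sdlineage infer --tree colony/tree.nwk --matrix colony/characters.csv \
    --locations colony/locations.csv --radius 6.68 --tau-end 216 --out run/
exec/sdlineage evaluate --fitted run/fitted.nwk --truth colony/truth.json \
    --out eval/
```

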