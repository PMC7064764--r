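# SymbioCycle

Quantitative tools for host-symbiont cell-cycle coordination in
cnidarian-dinoflagellate symbioses (e.g. the sea anemone Aiptasia,
*Exaiptasia pallida*, hosting *Breviolum* algae). The package is aimed
at cell and symbiosis biologists who image tentacles by confocal
microscopy and profile symbiont DNA content by flow cytometry, and
want the downstream analysis to be scripted and reproducible.

It implements two analyses end to end:

**1. 3D spatial colocalization of proliferation and symbionts.**
Multichannel z-stacks (Hoechst = all host nuclei, EdU = proliferating
nuclei, chlorophyll autofluorescence = symbionts) are segmented with an
anisotropic distance-transform watershed; per-tentacle statistics
include cell densities, the equivalent-sphere cell diameter
d = (6V/πN)^(1/3), cross-type k-nearest-neighbour distance
distributions (k = 1..12), tissue-layer depth profiles, and an
enrichment test of proliferating nuclei inside symbiont-containing
regions against a *neutral-dispersal* null: with f the fraction of
tentacle volume occupied by the union of symbiont bounding boxes, the
expected EdU+ count inside is f·(n_in + n_out); per-tentacle 2-cell
chi-square terms are pooled and a paired t-test compares observed and
expected inside-counts across tentacles.

**2. Dean-Jett-Fox cell-cycle deconvolution.** Propidium-iodide
DNA-content histograms are fit with a Gaussian G1 peak, a Gaussian
G2 peak (ratio fitted freely in [1.7, 2.3] so that "G2 at twice the G1
fluorescence" is a check, not an assumption), and an S compartment
uniform in DNA content convolved with the G1 measurement spread.
Doublets are removed beforehand by an idempotent forward-scatter-width
gate. Phase fractions are compared across conditions with
arcsine-square-root transformed two-way ANOVA and Tukey HSD.

Because raw images and FCS files for this system are rarely deposited,
the package ships a synthetic-data generator with known ground truth
(two-layer tentacle geometry, hard-core nucleus placement, Thomas-type
symbiont clusters, tunable EdU-symbiont proximity coupling; forward
Dean-Jett-Fox event model with doublets and debris), so every stage of
both pipelines is testable without downloads.

## Worked example

```r
library(SymbioCycle)

## a simulated, partially colonized tentacle with known ground truth
sc <- generateTentacleScene(sceneParams(seed = 1))

## segment all three channels, splitting touching cells
p <- detectParams()
nuclei   <- splitClusters(detectObjects(sc$stack, "hoechst",     p, "host_nuclei"), p)
edu      <- splitClusters(detectObjects(sc$stack, "edu",         p, "edu_nuclei"),  p)
symbiont <- splitClusters(detectObjects(sc$stack, "chlorophyll", p, "symbionts"),   p)
symbiont
#> ObjectSet < symbionts >: 284 objects, tentacle t1

## per-tentacle summary from the segmented objects
boxes <- boundingBoxes(symbiont)
vol   <- tentacleVolume(nuclei, dilationUm = 0)
tentacleSummary(nObjects(nuclei), nObjects(edu), nObjects(symbiont),
                vol$volume_um3, unionVolume(boxes))
#> host density 4.13e6 cells/mm^3, 10.4% EdU+, cell diameter 7.73 um, ...

## enrichment of proliferating nuclei inside symbiont regions
io <- insideOutsideCounts(edu, boxes)
neutralDispersalTest(data.frame(n_in = io[["n_in"]], n_out = io[["n_out"]],
                                v_sym = unionVolume(boxes),
                                v_total = vol$volume_um3))
#> EnrichmentResult over 1 tentacle(s)
#>   pooled chi-square = 5.544 (df = 1, p = 0.0185)

## cell-cycle deconvolution of simulated cytometry events
ev  <- generateCytometryEvents(histogramParams(f_g1 = 0.7, f_s = 0.2,
                                               f_g2m = 0.1, seed = 1))
fitDeanJettFox(gateSinglets(ev))
#> CellCycleFit: G1 69.6%  S 20.1%  G2/M 10.3%
#>   G1 peak 100 (CV 0.049), G2 peak 200 (CV 0.050), G2/G1 2.002
```

The 115 / 109 inside/outside split above is significantly enriched over
the ~97 EdU+ nuclei expected inside from the regions' 43% volume share
(the scene was simulated with proximity coupling turned on), and the
fitted phase fractions recover the simulated (70, 20, 10)% mixture
within half a percentage point.

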