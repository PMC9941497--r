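# perivasc

Sleep-cycle-dependent vessel dynamics and their predicted consequences for
cerebrospinal fluid (CSF) flow and solute transport in perivascular spaces
(PVS).

Penetrating arterioles in the cortex are sheathed by an annular,
CSF-filled perivascular space bounded externally by the astrocytic endfoot
tube. Across the sleep cycle the vessel lumen oscillates — slow vasomotion
(VLF 0.1–0.3 Hz, LF 0.3–1 Hz) that is largest in NREM and intermediate
sleep, a REM dilation that squeezes the PVS, a constriction with PVS
enlargement upon awakening — and those diameter changes pump CSF along the
PVS and stir solutes. `perivasc` is for researchers who want to go from
diameter time series (measured or simulated) to the predicted fluid
mechanics and transport: it generates synthetic recordings, extracts
diameters from two-photon *x–t* linescans, decomposes vasomotion into
frequency bands, scores sleep states from ECoG/EMG, and solves the flow
and transport models.

## The model at the core

The PVS is an annulus of length $L = 600\ \mu m$ between a moving inner
wall $R_v(t)$ and a fixed outer wall $R_{ast}$, with free cross-section
area following the measured oscillation law

$$A(t) = \langle A\rangle\Big(1 + \tfrac{a}{2}\cos\tfrac{2\pi t}{p}\Big) - \alpha\,\langle A\rangle_{baseline},$$

where $\langle A\rangle$, $a$ and $p$ are per-(vessel, state, band)
medians of the PVS area, its relative peak-to-trough oscillation
amplitude and the lumen peak-to-peak period, and $\alpha \in \{0, 0.25,
0.5\}$ is the obstructed fraction. At $Wo \lesssim 0.1$ and
$Re \sim 3\times10^{-3}$ the flow is quasi-steady Stokes
($\mu\nabla^2\mathbf u = \nabla p$, $\nabla\cdot\mathbf u = 0$), which for
axially uniform deformation reduces to $Q(y,t) = \dot A\,(L-y)$ with an
annular Poiseuille profile; solute transport
($\partial_t c + \mathbf u\cdot\nabla c = D\nabla^2 c$) is solved on the
deforming annulus by a conservative finite-volume scheme, yielding the
oscillatory dispersion enhancement $100\,(D_{eff}-D)/D$ and the depth of
the concentration front (level 0.1) under an entrance concentration of 1.

## Worked example

From a synthetic sleep recording to predicted transport:

```r
library(perivasc)

h  <- makeHypnogram(nCycles = 2, seed = 1)           # WBS-NREM-IS-REM-WAS
tr <- makeVesselTrace(h, vesselParams(fs = 50), seed = 2)
tr
#> VesselTrace v1 (penetrating_arteriole)
#>   23500 samples at 50 Hz (470.0 s)
#>   lumen 16.70 um, endfoot 24.37 um, PVS width 7.69 um (medians)

bs <- summarizeEpisodes(tr, h)                       # band summaries
subset(bs, state == "NREM" & band == "VLF")
#>  vessel_id state band      a_rel   p_pp_s A_med_um2 r_lumen_um r_endfoot_um n_episodes
#>         v1  NREM  VLF 0.01577675 5.035833  247.6774   8.138837      12.0479          2
```

The NREM VLF row says: the PVS area (median 248 μm²) oscillates with a
relative peak-to-trough amplitude of 1.6 % every 5.0 s. Feed it to the
flow and transport models with 25 % of the baseline PVS obstructed:

```r
m <- modelFromSummary(bs, state = "NREM", band = "VLF", alpha = 0.25,
                      baselineState = "WBS")
flow <- solvePvsFlow(m)
c(u_peak = peakVelocity(flow), dp_Pa = pressureDrop(flow)$dp_Pa,
  grad_Pa_mm = pressureDrop(flow)$grad_Pa_mm)
#> u_peak_um_s       dp_Pa  grad_Pa_mm
#>       11.89        2.60        4.34

disp <- dispersionEnhancement(m, knownSolutes()$dex70)   # 70 kDa dextran
c(D_eff = disp@D_eff, enhancement_pct = disp@enhancement)
#>           D_eff enhancement_pct
#>          17.016           0.095

infl <- influxFront(m, knownSolutes()$dex70, depth = 100, Tmax = 300)
ref  <- influxFront(m, knownSolutes()$dex70, flowOn = FALSE, depth = 100,
                    Tmax = 300)
c(t_front_s = infl@t_front, t_diffusion_s = ref@t_front)
#>     t_front_s t_diffusion_s
#>          95.1         108.7
```

Reading the output: this vessel's NREM slow vasomotion drives CSF at a
peak velocity of ~12 μm/s with a ~2.6 Pa pressure difference along the
600 μm PVS, enhances the effective diffusivity of 70 kDa dextran by
~0.1 % over its molecular value of 17 μm²/s, and carries the solute
front to 100 μm depth in 95 s versus 109 s by diffusion alone. Larger
oscillation amplitudes (the generator's NREM default is deliberately
conservative once translated into area units) strengthen all three
effects; see the vignette in `vignettes/perivascular-transport.Rmd` for
the model's assumptions and the numerical choices.

Other entry points: `makeLinescan()`/`downsampleStack()`/`traceEdges()`
for synthetic linescan extraction, `makeEcogEmg()`/`scoreSleepStates()`
for sleep scoring, and `cardiacScenario()` for cardiac-pulsation
scenarios calibrated to a target peak velocity.

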