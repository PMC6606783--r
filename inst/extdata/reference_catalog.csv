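name,chain,citation
Trichoaureocin 1d,Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Vxx-Ala-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol,Brueckner et al. 2009
Longibrachin A I,Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Vxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol,Leclerc et al. 1998
Longibrachin A II,Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Vxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Pheol,Leclerc et al. 1998
Longibrachin A III,Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Vxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol,Leclerc et al. 1998
Longibrachin A IV,Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Vxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Pheol,Leclerc et al. 1998
Longibrachin B II,Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Vxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Glu-Gln-Pheol,Leclerc et al. 1998
Longibrachin B III,Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Vxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Vxx-Glu-Gln-Pheol,Leclerc et al. 1998
Trilongin CIII,Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Vxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Glu-Gln-Pheol,Mikkola et al. 2012
Trilongin CIV,Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Vxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Vxx-Glu-Gln-Pheol,Mikkola et al. 2012
Suzukacillin A 12,Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Lxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Pheol,Krause et al. 2006
Trichosporin TS-B-VIa,Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Lxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol,Iida et al. 1990
Trichosporin TS-B-IVc,Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Vxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol,Iida et al. 1990
Paracelsin A,Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Vxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol,Pocsfalvi et al. 1998
Paracelsin B,Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Lxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol,Pocsfalvi et al. 1998
Paracelsin C,Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Vxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol,Pocsfalvi et al. 1998
Paracelsin D,Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Lxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol,Pocsfalvi et al. 1998
Paracelsin F,Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Vxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Pheol,Pocsfalvi et al. 1998
Paracelsin H,Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Lxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Pheol,Pocsfalvi et al. 1998
Saturnisporin SA IV,Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Lxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Pheol,Rebuffat et al. 1993
Trichocellin TC-B-I,Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Lxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Aib-Glu-Gln-Pheol,Wada et al. 1995
Trichocellin TC-B-II,Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Lxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Vxx-Glu-Gln-Pheol,Wada et al. 1995
Trichoderma citrinoviride sequence 1,Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Lxx-Aib-Gly-Ala-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Pheol,Maddau et al. 2009
Trichoderma citrinoviride sequence 4,Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Lxx-Aib-Gly-Vxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol,Maddau et al. 2009
Trichoderma citrinoviride sequence 5,Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Lxx-Aib-Gly-Vxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Pheol,Maddau et al. 2009
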