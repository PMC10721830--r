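family,genus,species,wd_g_cm3
Lecythidaceae,Eschweilera,coriacea,0.81
Lecythidaceae,Eschweilera,wachenheimii,0.84
Lecythidaceae,Gustavia,elliptica,0.63
Sapotaceae,Pouteria,anomala,0.74
Sapotaceae,Pouteria,guianensis,0.79
Sapotaceae,Micropholis,guyanensis,0.65
Burseraceae,Protium,apiculatum,0.58
Burseraceae,Protium,hebetatum,0.61
Chrysobalanaceae,Licania,oblongifolia,0.78
Chrysobalanaceae,Couepia,longipendula,0.72
Fabaceae,Swartzia,reticulata,0.85
Fabaceae,Inga,paraensis,0.62
Fabaceae,Dinizia,excelsa,0.89
Fabaceae,Tachigali,venusta,0.54
Urticaceae,Cecropia,sciadophylla,0.36
Urticaceae,Pourouma,guianensis,0.42
Hypericaceae,Vismia,cayennensis,0.45
Hypericaceae,Vismia,guianensis,0.43
Melastomataceae,Bellucia,grossularioides,0.55
Melastomataceae,Miconia,burchellii,0.60
Goupiaceae,Goupia,glabra,0.71
Lauraceae,Ocotea,cernua,0.52
Lauraceae,Licaria,cannella,0.76
Moraceae,Brosimum,parinarioides,0.64
Moraceae,Helicostylis,scabra,0.66
Myristicaceae,Virola,calophylla,0.47
Myristicaceae,Iryanthera,juruensis,0.59
Arecaceae,Oenocarpus,bacaba,0.48
Euphorbiaceae,Micrandropsis,scleroxylon,0.82
Malvaceae,Scleronema,micranthum,0.62
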