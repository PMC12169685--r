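compound_id,heteroaryl_name,EA_eV,LUMO_eV,lumo_coef_Cbeta,lumo_coef_Calpha,npa_Cbeta,c13_Cbeta_ppm,h1_Hbeta1_ppm,dihedral_deg,nics0zz_ppm,nics1zz_ppm,sigma_het,pKa_conjugate_acid,EA_protonated_eV,t_half_min,dG_dft_kcal_mol,outlier,outlier_reason,provenance
1a,pyridin-3-yl,NA,NA,NA,NA,NA,118.0,5.50,NA,NA,NA,NA,NA,NA,452,NA,FALSE,,main-text+characterization
1b,pyrimidin-5-yl,NA,NA,NA,NA,NA,119.1,5.56,NA,NA,NA,NA,NA,NA,80,NA,FALSE,,main-text+characterization
1c,thiophen-2-yl,NA,NA,NA,NA,NA,117.7,5.48,NA,NA,NA,NA,NA,NA,651,NA,FALSE,,main-text+characterization
1d,thiophen-3-yl,NA,NA,NA,NA,NA,116.9,5.43,NA,NA,NA,NA,NA,NA,1733,NA,FALSE,,main-text+characterization
1e,5-(1-methyl-1H)-imidazolyl,NA,NA,NA,NA,NA,118.2,5.49,NA,NA,NA,NA,NA,NA,264,NA,FALSE,,main-text+characterization
1f,6-(trifluoromethyl)pyridin-2-yl,NA,NA,NA,NA,NA,118.6,5.52,NA,NA,NA,NA,NA,NA,25,NA,TRUE,run in 100% DMSO-d6 (solubility),main-text+characterization
1g,2-(trifluoromethyl)pyrimidin-5-yl,NA,NA,NA,NA,NA,120.2,5.62,NA,NA,NA,NA,NA,NA,22,NA,FALSE,,main-text+characterization
1h,1-methyl-1H-pyrazol-4-yl,NA,NA,NA,NA,NA,116.3,5.40,NA,NA,NA,NA,NA,NA,6188,NA,FALSE,,main-text+characterization
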