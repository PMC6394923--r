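study_id,pathway,design,regimen,n,median_dfs,median_os
AlSukhun_NAT,NAT,phase2,CRT+surgery,20,,13.4
Cardenes_NAT,NAT,phase2,CRT+surgery,28,,10.3
Casadei_NAT,NAT,phase2,CRT+surgery,18,,28.3
Cetin_NAT,NAT,phase2,CRT+surgery,11,,
Chakraborty_NAT,NAT,phase2,CRT+surgery,13,2.4,9.1
Crane_NAT,NAT,phase2,CRT+surgery,69,,19.2
Epelbaum_NAT,NAT,phase2,CRT+surgery,20,,8
Esnaola_NAT,NAT,phase2,CRT+surgery,37,10.4,11.8
Evans_NAT,NAT,phase2,CRT+surgery,86,15.4,22.7
Fiore_NAT,NAT,phase2,CRT+surgery,34,20,19.2
Golcher2012_NAT,NAT,phase2,CRT+surgery,121,,
Golcher2015_NAT,NAT,phase2,CRT+surgery,33,8.4,17.4
Heinrich_NAT,NAT,phase2,CT+surgery,28,9.2,26.5
Herman_NAT,NAT,phase2,CRT+surgery,49,7.8,13.9
Hong_NAT,NAT,phase2,CRT+surgery,50,10.4,17.3
Jang_NAT,NAT,phase2,CRT+surgery,27,,21
Jensen_NAT,NAT,phase2,CRT+surgery,23,,11.5
Joensuu_NAT,NAT,phase2,CRT+surgery,33,18,25
Kim_NAT,NAT,phase2,CRT+surgery,68,,18.2
Landry_NAT,NAT,phase2,CRT+surgery,21,14.2,19.4
Laurent_NAT,NAT,phase2,CRT+surgery,22,8,17
LeScodan_NAT,NAT,phase2,CRT+surgery,41,,9.4
Lee_NAT,NAT,phase2,CT+surgery,43,10,16.6
Leone_NAT,NAT,phase2,CRT+surgery,39,10.2,16.7
Lin_NAT,NAT,phase2,CRT+surgery,42,,10.3
Lind_NAT,NAT,phase2,CRT+surgery,17,,19
Magnin_NAT,NAT,phase2,CRT+surgery,32,,16
Magnino_NAT,NAT,phase2,CRT+surgery,23,,14
Marti_NAT,NAT,phase2,CRT+surgery,26,7,13
Mattiucci_NAT,NAT,phase2,CRT+surgery,40,,15.5
Massucco_NAT,NAT,phase2,CRT+surgery,28,10,15.4
Maximous_NAT,NAT,phase2,CRT+surgery,25,,12
Mornex_NAT,NAT,phase2,CRT+surgery,41,,9.4
Motoi_NAT,NAT,phase2,CT+surgery,35,,19.7
Moutardier_NAT,NAT,phase2,CRT+surgery,19,,20
OReilly_NAT,NAT,phase2,CT+surgery,38,,27.2
Palmer_NAT,NAT,phase2,CT+surgery,50,,13.6
Pipas_NAT,NAT,phase2,CRT+surgery,37,,17.3
Pister_NAT,NAT,phase2,CRT+surgery,37,,12
Sahora_NAT,NAT,phase2,CT+surgery,25,,16
Satoi_NAT,NAT,phase2,CRT+surgery,35,,24.5
Sherman_NAT,NAT,phase2,CRT+surgery v CT+surgery,45,34,
Small_NAT,NAT,phase2,CRT+surgery,29,9.9,11.8
Talamonti_NAT,NAT,phase2,CRT+surgery,20,,
Tinchon_NAT,NAT,phase2,CT+surgery,12,,
Turrini_NAT,NAT,phase2,CRT+surgery,34,,15.5
VanBuren_NAT,NAT,phase2,CRT+surgery,59,6.6,16.8
Varadhachary_NAT,NAT,phase2,CRT+surgery,90,13.2,17.4
Vento_NAT,NAT,phase2,CRT+surgery,22,,30.2
Wilkowski_NAT,NAT,phase2,CRT+surgery,93,5.6,9.3
Regine_SF_a,SF,RCT,Surgery+CRT,230,,17.1
Neoptolemos2004_SF_a,SF,RCT,Surgery+CT,551,14.1,23
VanLaethem_SF_a,SF,RCT,Surgery+CRT,45,11.8,24.3
Schmidt_SF_a,SF,RCT,Surgery+CRT,53,15.2,26.5
Reni_SF_a,SF,RCT,Surgery+CRT,51,11.7,26.2
Yoshitomi_SF_a,SF,RCT,Surgery+CT,49,12,29.8
Shimoda_SF_a,SF,RCT,Surgery+CT,29,14.6,21.5
Uesaka_SF_a,SF,RCT,Surgery+CT,187,22.9,46.5
Neoptolemos2009_SF_a,SF,RCT,Surgery+CRT,145,10.7,15.9
Ueno_SF_a,SF,RCT,Surgery+CT,58,11.4,22.3
Oettle_SF_a,SF,RCT,Surgery+CT,179,13.4,22.8
Kosuge_SF_a,SF,RCT,Surgery+CT,45,8.6,12.5
Smeenk_SF_a,SF,RCT,Surgery+CRT,110,18,21.6
Morak_SF_a,SF,RCT,Surgery+CR,59,12,19
Neoptolemos2010_SF_a,SF,RCT,Surgery+CT,366,,25.5
Regine_SF_b,SF,RCT,Surgery+CRT,221,,20.5
Neoptolemos2004_SF_b,SF,RCT,Surgery+CT,537,14.3,23.6
VanLaethem_SF_b,SF,RCT,Surgery+CT,45,10.9,24.4
Schmidt_SF_b,SF,RCT,Surgery+CT,57,11.5,28.5
Reni_SF_b,SF,RCT,Surgery+CT,49,15.2,31.6
Yoshitomi_SF_b,SF,RCT,Surgery+CT,50,2.3,21.2
Shimoda_SF_b,SF,RCT,Surgery+CT,28,10.5,18
Uesaka_SF_b,SF,RCT,Surgery+CT,190,11.3,25.5
Neoptolemos2009_SF_b,SF,RCT,Surgery+CT,147,15.3,20.1
Ueno_SF_b,SF,RCT,Surgery only,60,5,18.4
Oettle_SF_b,SF,RCT,Surgery only,175,6.7,20.2
Kosuge_SF_b,SF,RCT,Surgery only,44,10.2,15.8
Smeenk_SF_b,SF,RCT,Surgery only,108,14.4,19.2
Morak_SF_b,SF,RCT,Surgery only,61,7,18
Neoptolemos2010_SF_b,SF,RCT,Surgery+CT,364,,28
AlSukhun_SF,SF,phase2,Surgery+adjuvant,21,,18.1
Casadei_SF,SF,phase2,Surgery+adjuvant,20,,27.5
Golcher2012_SF,SF,phase2,Surgery+adjuvant,58,,21
Golcher2015_SF,SF,phase2,Surgery+adjuvant,33,8.7,14.4
Lind_SF,SF,phase2,Surgery+adjuvant,35,,11
Massucco_SF,SF,phase2,Surgery+adjuvant,44,8,14
Satoi_SF,SF,phase2,Surgery+adjuvant,41,,18.5
Vento_SF,SF,phase2,Surgery+adjuvant,25,,35.9
Jang_SF,SF,phase2,Surgery+adjuvant,23,,12
DeGus2016_SF,SF,cohort,Surgery+adjuvant,6840,,24.2
Mellon_SF,SF,cohort,Surgery+adjuvant,241,,22.1
Nurmi_SF,SF,cohort,Surgery+adjuvant,150,13,26
Shubert_SF,SF,cohort,Surgery+adjuvant,216,,13
Artinya_SF,SF,cohort,Surgery+adjuvant,419,,19
Ielpo_SF,SF,cohort,Surgery+adjuvant,36,,22.1
Roland_SF,SF,cohort,Surgery+adjuvant,85,,
DeGus2017_SF,SF,cohort,Surgery+adjuvant,11316,,
Mokdad_SF,SF,cohort,Surgery+adjuvant,6015,,21
Chen_SF,SF,cohort,Surgery+adjuvant,98,,17
Tzeng_SF,SF,cohort,Surgery+adjuvant,52,,25.3
Fujii2015_SF,SF,cohort,Surgery+adjuvant,71,,13.1
Fujii2017_SF,SF,cohort,Surgery+adjuvant,416,,
Papalezova_SF,SF,cohort,Surgery+adjuvant,92,,13
Hirono_SF,SF,cohort,Surgery+adjuvant,124,,13.7
Murakami_SF,SF,cohort,Surgery+adjuvant,25,,11.6
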