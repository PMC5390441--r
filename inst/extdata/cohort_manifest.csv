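acronym,study_name,study_type,n_variables,n_participants,use
AIR,Atherosclerosis and Insulin Resistance study,general population,136,435,construction
ARIC,Atherosclerosis risk in communities,general population,10108,15042,validation
BCAPS,Beta-blocker Cholesterol-lowering Asymptomatic Plaque Study,RCT,134,1544,validation
BHS,Bogalusa Heart Study,general population,1220,1986,construction
BKRE,Konyang University Hospital CIMT Registry,RCT,109,205,validation
Bruneck,Bruneck Study,general population,141,821,validation
CAPS,Carotid Atherosclerosis Progression Study,general population,692,6972,construction
CCCC,Chin-Shan Community Cardiovascular Cohort Study,general population,110,3603,construction
CHS,Cardiovascular Health Study,general population,1426,5901,construction
CIMT_TIME,CIMT TIME Project,risk population,144,671,validation
CMCS-Beijing,Chinese Multi-provincial Cohort Study-Beijing,general population,141,1324,construction
CREED,Cardiovascular Risk Extended Evaluation in Dialysis patients,risk population,53,138,construction
DIWA,Diabetes Impaired glucose tolerance in Women and Atherosclerosis,general population,129,644,validation
EAS,Edinburgh Artery Study,general population,74,1593,construction
Ekart et al.,None,risk population,102,54,construction
EPICARDIAN,Cardiovascular Epidemiology in the Elderly in Spain,general population,76,446,construction
EVA,Etude du Vieillissement Arteriel,general population,212,1135,validation
HD-IMT,Carotid ultrasonographic parameters in patients on hemodialysis,risk population,130,85,validation
HOORN,The Hoorn Study,general population,128,3103,construction
IMPROVE,Carotid IMT and IMT-Progression as Predictors of Vascular Events,risk population,103,3703,construction
INVADE,Interventionsprojekt zerebrovaskulaere Erkrankungen und Demenz,general population,1581,3365,validation
Kato et al.,None,risk population,131,284,validation
KIHD,Kuopio Ischemic Heart Disease Risk Factor Study,general population,151,1399,construction
Landecho et al.,None,risk population,69,248,validation
Niguarda,Niguarda-Monzino Study,risk population,88,1564,construction
NOMAS/INVEST,Northern Manhattan Study,general population,334,857,validation
OSACA,Osaca Follow-Up Study for Carotid Atherosclerosis,risk population,108,291,construction
Papagianni et al.,None,risk population,73,84,construction
PIVUS,Prospective Investigation of the Vasculature in Uppsala Seniors,general population,98,1017,validation
PLIC,Progression of Lesions in the Intima of the Carotid,general population,264,2607,validation
RIAS,Resistive Index in AtheroSclerosis,risk population,67,158,construction
Rotterdam,Rotterdam Study,general population,34,7983,validation
SAPHIR,Salzburg Atherosclerosis Prevention program,general population,141,3127,validation
SHIP,Study of Health in Pomerania,general population,320,4308,construction
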