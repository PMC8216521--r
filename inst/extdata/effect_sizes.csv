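family,item,prevalence,initiation,cessation,note
price,elasticity_ages_14_17,-0.40,NA,NA,price elasticity of prevalence
price,elasticity_ages_18_24,-0.30,NA,NA,price elasticity of prevalence
price,elasticity_ages_25_34,-0.20,NA,NA,price elasticity of prevalence
price,elasticity_ages_35_64,-0.10,NA,NA,price elasticity of prevalence
price,elasticity_ages_65p,-0.20,NA,NA,price elasticity of prevalence
smoke_free,worksite,-0.06,-0.06,0.06,indoor worksite ban; coverage and enforcement scaled
smoke_free,restaurant,-0.02,-0.02,0.02,restaurant ban; coverage and enforcement scaled
smoke_free,bar,-0.01,-0.01,0.01,pub and bar ban; coverage and enforcement scaled
smoke_free,other,-0.01,-0.01,0.01,other public place bans; coverage and enforcement scaled
media_campaign,none,0,0,0,no campaign
media_campaign,low,-0.0163,-0.0163,0.0163,sporadic non-TV publicity
media_campaign,medium,-0.0325,-0.0325,0.0325,sporadic TV plus other media
media_campaign,high,-0.065,-0.065,0.065,heavy TV social-marketing campaign
marketing_restrictions,none,0,0,0,no restrictions
marketing_restrictions,minimal,-0.01,-0.01,0,partial broadcast/print ban
marketing_restrictions,moderate,-0.03,-0.04,0.02,all media plus one indirect medium
marketing_restrictions,comprehensive,-0.05,-0.08,0.04,all direct and indirect marketing
health_warnings,none,0,0,0,no warnings
health_warnings,low,-0.01,-0.01,0.02,under 30% of pack; not bold or graphic
health_warnings,moderate,-0.02,-0.02,0.04,at least 30% of pack
health_warnings,high,-0.04,-0.06,0.10,large bold graphic; at least 50% of pack
cessation_treatment,pharmacotherapy,-0.01,0,0.06,NRT/bupropion/varenicline legal
cessation_treatment,financial_coverage,-0.0225,0,0.12,treatment reimbursement; publicity discounted
cessation_treatment,quitline,-0.0075,0,0.075,active with follow-up; tier scaled
cessation_treatment,brief_intervention,-0.01,0,0.08,provider advice; scaled by index
cessation_treatment,all_combined,-0.0515,0,0.427,full availability and reimbursement bundle
youth_access,strong_ages_14_15,-0.24,-0.24,0,frequent checks; potent publicized penalties
youth_access,strong_ages_16_17,-0.16,-0.16,0,frequent checks; potent publicized penalties
youth_access,moderate_ages_14_15,-0.12,-0.12,0,regular checks with publicity
youth_access,moderate_ages_16_17,-0.08,-0.08,0,regular checks with publicity
youth_access,low_ages_14_15,-0.03,-0.03,0,sporadic checks; weak penalties
youth_access,low_ages_16_17,-0.02,-0.02,0,sporadic checks; weak penalties
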